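#' @title Pedigree-driven Mendelian inheritance analyses
#' @description Seven family-based inheritance analyses over a trio
#'   (child/father/mother): autosomal de novo, autosomal dominant, autosomal
#'   recessive, compound heterozygous, X-linked de novo, X-linked dominant
#'   and X-linked recessive. Rules are encoded as a data structure
#'   ([inheritance_rules()]) interpreted by [evaluate_inheritance()], so a
#'   revised rule set is a data change, not a code change.
#' @name mendelian
NULL

MENDELIAN_MODELS <- c("autosomal_de_novo", "autosomal_dominant",
                      "autosomal_recessive", "compound_heterozygous",
                      "x_linked_de_novo", "x_linked_dominant",
                      "x_linked_recessive")

#' Load a PLINK-style 6-column pedigree file
#'
#' Columns: family id, individual id, father id, mother id, sex (1=male,
#' 2=female, other=unknown), phenotype (2=affected, 1=unaffected,
#' other=unknown). Parent ids must be `"0"` or reference another record.
#'
#' @param ped_path path to the PED file (whitespace-delimited).
#' @return data frame with columns `family_id`, `sample_id`, `father_id`,
#'   `mother_id`, `sex`, `affected`.
#' @export
load_pedigree <- function(ped_path) {
  lines <- readLines(ped_path, warn = FALSE)
  lines <- lines[nchar(trimws(lines)) > 0 & !startsWith(lines, "#")]
  recs <- lapply(seq_along(lines), function(i) {
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 6) {
      stop("PED line ", i, ": expected 6 columns, found ", length(f))
    }
    list(family_id = f[1], sample_id = f[2], father_id = f[3],
         mother_id = f[4],
         sex = switch(f[5], "1" = "male", "2" = "female", "unknown"),
         affected = switch(f[6], "2" = "affected", "1" = "unaffected", "unknown"))
  })
  ped <- do.call(rbind, lapply(recs, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  if (anyDuplicated(paste(ped$family_id, ped$sample_id))) {
    stop("duplicate sample id within a family in ", ped_path)
  }
  for (i in seq_len(nrow(ped))) {
    for (p in c("father_id", "mother_id")) {
      pid <- ped[[p]][i]
      if (pid != "0" && !pid %in% ped$sample_id) {
        stop("PED line ", i, ": ", p, " '", pid, "' does not reference a record")
      }
    }
  }
  ped
}

#' Derive the trio structure from a pedigree
#'
#' @param pedigree data frame from [load_pedigree()].
#' @return list with `child`, `father`, `mother`, `child_sex`, and the three
#'   affected statuses.
#' @export
derive_trio <- function(pedigree) {
  has_both <- pedigree$father_id != "0" & pedigree$mother_id != "0"
  if (!any(has_both)) stop("pedigree contains no individual with both parents")
  ch <- pedigree[which(has_both)[1], ]
  fa <- pedigree[pedigree$sample_id == ch$father_id, ][1, ]
  mo <- pedigree[pedigree$sample_id == ch$mother_id, ][1, ]
  if (fa$sex == "female") stop("father ", fa$sample_id, " is recorded as female")
  if (mo$sex == "male") stop("mother ", mo$sample_id, " is recorded as male")
  list(child = ch$sample_id, father = fa$sample_id, mother = mo$sample_id,
       child_sex = ch$sex,
       affected = c(child = ch$affected, father = fa$affected,
                    mother = mo$affected))
}

check_pedigree_samples <- function(pedigree, vcf_samples) {
  missing <- setdiff(pedigree$sample_id, vcf_samples)
  if (length(missing)) {
    stop("pedigree sample(s) absent from the VCF header: ",
         paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' The normative inheritance rule tables
#'
#' One entry per model. Member constraints are sets of allowed genotype
#' classes, possibly conditioned on sex or affected status; a revised rule
#' set only needs to replace this data structure.
#'
#' @return named list of rule tables.
#' @export
inheritance_rules <- function() {
  list(
    autosomal_de_novo = list(
      chrom = "autosome", child_affected_required = TRUE,
      child = list(any = "HET"),
      father = list(any = "HOM_REF"),
      mother = list(any = "HOM_REF")),
    autosomal_dominant = list(
      chrom = "autosome", child_affected_required = TRUE,
      requires_affected_parent = TRUE,
      child = list(any = "HET"),
      parent_affected = "HET",
      parent_unaffected = "HOM_REF"),
    autosomal_recessive = list(
      chrom = "autosome", child_affected_required = TRUE,
      child = list(any = "HOM_ALT"),
      father = list(any = "HET"),
      mother = list(any = "HET")),
    compound_heterozygous = list(   # per-site candidate rule
      chrom = "autosome", child_affected_required = TRUE,
      child = list(any = "HET"),
      single_carrier_parent = TRUE,
      carrier = c("HET", "HOM_ALT"), noncarrier = "HOM_REF"),
    x_linked_de_novo = list(
      chrom = "X", child_affected_required = TRUE,
      child = list(male = "HOM_ALT", female = "HET"),
      father = list(any = "HOM_REF"),
      mother = list(any = "HOM_REF")),
    x_linked_dominant = list(
      chrom = "X", child_affected_required = TRUE,
      requires_affected_parent = TRUE,
      child = list(male = "HOM_ALT", female = "HET"),
      parent_affected_father = "HOM_ALT",
      parent_affected_mother = "HET",
      parent_unaffected = "HOM_REF"),
    x_linked_recessive = list(
      chrom = "X", child_affected_required = TRUE,
      by_child_sex = list(
        male = list(child = "HOM_ALT", father = "HOM_REF", mother = "HET"),
        female = list(child = "HOM_ALT", father = "HOM_ALT", mother = "HET")))
  )
}

class_ok <- function(cls, allowed, permissive) {
  if (identical(cls, "MISSING")) return(isTRUE(permissive))
  cls %in% allowed
}

#' Evaluate one inheritance model on a trio of genotype classes
#'
#' Returns the rule-table verdict for the given child/father/mother genotype
#' classes. X-linked models require `chrom_is_X = TRUE` and autosomal models
#' require `chrom_is_X = FALSE`; a mismatch returns `FALSE`. In strict mode
#' (default) any `MISSING` member fails the rule; in permissive mode a
#' missing genotype acts as a wildcard. For `compound_heterozygous` the
#' verdict is the per-site candidate rule (child het, exactly one carrier
#' parent); pairing across sites is done by [find_compound_het()].
#'
#' @param model one of the seven model names.
#' @param child_gt_class,father_gt_class,mother_gt_class genotype classes
#'   from [classify_genotype()] (hemizygous male X calls normalized to
#'   `HOM_REF`/`HOM_ALT` beforehand, see [normalize_hemizygous()]).
#' @param chrom_is_X whether the variant lies on the X chromosome.
#' @param child_sex `"male"`, `"female"`, or `"unknown"`.
#' @param affected named statuses (`child`, `father`, `mother`), each
#'   `"affected"`, `"unaffected"` or `"unknown"`.
#' @param permissive treat `MISSING` as a wildcard instead of failing.
#' @param rules rule-table data (defaults to [inheritance_rules()]).
#' @return `TRUE` or `FALSE`.
#' @export
evaluate_inheritance <- function(model, child_gt_class, father_gt_class,
                                 mother_gt_class, chrom_is_X = FALSE,
                                 child_sex = "female",
                                 affected = c(child = "affected",
                                              father = "unaffected",
                                              mother = "unaffected"),
                                 permissive = FALSE,
                                 rules = inheritance_rules()) {
  model <- match.arg(model, MENDELIAN_MODELS)
  rule <- rules[[model]]
  if (rule$chrom == "X" && !chrom_is_X) return(FALSE)
  if (rule$chrom == "autosome" && chrom_is_X) return(FALSE)

  if (isTRUE(rule$child_affected_required) &&
      affected[["child"]] == "unaffected") return(FALSE)

  member_allowed <- function(constraint, sex) {
    if (!is.null(constraint$any)) return(constraint$any)
    if (sex %in% names(constraint)) return(constraint[[sex]])
    NULL   # sex-dependent constraint with unknown sex
  }

  if (!is.null(rule$by_child_sex)) {
    sub <- rule$by_child_sex[[child_sex]]
    if (is.null(sub)) return(FALSE)
    return(class_ok(child_gt_class, sub$child, permissive) &&
           class_ok(father_gt_class, sub$father, permissive) &&
           class_ok(mother_gt_class, sub$mother, permissive))
  }

  allowed_child <- member_allowed(rule$child, child_sex)
  if (is.null(allowed_child)) return(FALSE)
  if (!class_ok(child_gt_class, allowed_child, permissive)) return(FALSE)

  if (isTRUE(rule$single_carrier_parent)) {
    fa_car <- class_ok(father_gt_class, rule$carrier, permissive)
    mo_car <- class_ok(mother_gt_class, rule$carrier, permissive)
    fa_ref <- class_ok(father_gt_class, rule$noncarrier, permissive)
    mo_ref <- class_ok(mother_gt_class, rule$noncarrier, permissive)
    return((fa_car && mo_ref) || (mo_car && fa_ref))
  }

  if (!is.null(rule$parent_affected) || !is.null(rule$parent_affected_father)) {
    n_affected <- 0L
    for (p in c("father", "mother")) {
      gt <- if (p == "father") father_gt_class else mother_gt_class
      st <- affected[[p]]
      if (st == "affected") {
        allowed <- rule$parent_affected %||%
          rule[[paste0("parent_affected_", p)]]
        if (!class_ok(gt, allowed, permissive)) return(FALSE)
        n_affected <- n_affected + 1L
      } else if (st == "unaffected") {
        if (!class_ok(gt, rule$parent_unaffected, permissive)) return(FALSE)
      } else {
        return(FALSE)   # unknown parent status is not actionable
      }
    }
    if (isTRUE(rule$requires_affected_parent) && n_affected == 0L) return(FALSE)
    return(TRUE)
  }

  class_ok(father_gt_class, rule$father$any, permissive) &&
    class_ok(mother_gt_class, rule$mother$any, permissive)
}

#' Normalize a hemizygous male X genotype
#'
#' Haploid calls on the male X (`"1"`, `"0"`, `"."`) are mapped to
#' `HOM_ALT` / `HOM_REF` / `MISSING`; diploid calls keep their
#' [classify_genotype()] class (so `"1/1"` is also accepted as hemizygous
#' alt).
#'
#' @param gt_raw raw GT string.
#' @param gt_class class from [classify_genotype()] (recomputed if missing).
#' @return a genotype class string.
#' @export
normalize_hemizygous <- function(gt_raw, gt_class = classify_genotype(gt_raw)) {
  al <- strsplit(gt_raw, "[/|]")[[1]]
  if (length(al) == 1) {
    if (al == ".") return("MISSING")
    if (al == "0") return("HOM_REF")
    return("HOM_ALT")
  }
  gt_class
}

is_x_contig <- function(chrom) chrom %in% c("X", "chrX")

# Reconstruct the trio's genotype classes for one document; absence of a
# sample entry means hom-ref (sparsity convention). Quality gates demote a
# stored entry to MISSING.
trio_classes <- function(doc, trio, min_dp = NULL, min_gq = NULL) {
  on_x <- is_x_contig(doc$chrom)
  sexes <- c("unknown", "male", "female")
  get <- function(sid, sex) {
    e <- NULL
    for (se in doc$sample_entries) {
      if (se$sample_id == sid) { e <- se; break }
    }
    if (is.null(e)) return(list(class = "HOM_REF", raw = "0/0"))
    cls <- e$gt_class
    if (on_x && sex == "male") cls <- normalize_hemizygous(e$gt_raw, cls)
    if (!is.null(min_dp)) {
      dp <- e$format_values[["DP"]]
      if (is.null(dp) || dp < min_dp) cls <- "MISSING"
    }
    if (!is.null(min_gq)) {
      gq <- e$format_values[["GQ"]]
      if (is.null(gq) || gq < min_gq) cls <- "MISSING"
    }
    list(class = cls, raw = e$gt_raw)
  }
  father_sex <- "male"; mother_sex <- "female"
  list(child = get(trio$child, trio$child_sex),
       father = get(trio$father, father_sex),
       mother = get(trio$mother, mother_sex),
       on_x = on_x)
}

doc_gene_symbols <- function(doc, gene_field = "SYMBOL") {
  g <- unique(unlist(lapply(doc$transcript_annotations, `[[`, gene_field)))
  g[!is.na(g) & nchar(g) > 0]
}

#' Run a Mendelian inheritance analysis over a store
#'
#' Every variant document is evaluated against the trio reconstructed from
#' the pedigree (absent sample entries are hom-ref). X-linked models are
#' restricted to the X chromosome (contig `X` or `chrX`), autosomal models
#' to every other contig. Optional quality gates demote low-quality
#' genotypes to missing, which fails the rule in strict mode.
#'
#' @param store a `vs_store`.
#' @param pedigree data frame from [load_pedigree()].
#' @param model one of the seven model names (for
#'   `compound_heterozygous` use [find_compound_het()], which this function
#'   dispatches to, returning pairs).
#' @param min_dp,min_gq optional per-genotype quality gates.
#' @param permissive treat missing genotypes as wildcards.
#' @param gene_field transcript field holding the gene symbol.
#' @return data frame of hits: model, chrom, pos, ref, alt, the three
#'   genotype classes, and gene symbol (NA when unannotated).
#' @export
run_mendelian <- function(store, pedigree, model, min_dp = NULL, min_gq = NULL,
                          permissive = FALSE, gene_field = "SYMBOL") {
  model <- match.arg(model, MENDELIAN_MODELS)
  if (model == "compound_heterozygous") {
    return(find_compound_het(store, pedigree, gene_field = gene_field,
                             min_dp = min_dp, min_gq = min_gq,
                             permissive = permissive))
  }
  trio <- derive_trio(pedigree)
  check_pedigree_samples(pedigree, store$schema$samples)
  wants_x <- inheritance_rules()[[model]]$chrom == "X"
  hits <- list()
  for (doc in store_docs(store)) {
    on_x <- is_x_contig(doc$chrom)
    if (on_x != wants_x) next
    tc <- trio_classes(doc, trio, min_dp, min_gq)
    ok <- evaluate_inheritance(model, tc$child$class, tc$father$class,
                               tc$mother$class, chrom_is_X = on_x,
                               child_sex = trio$child_sex,
                               affected = trio$affected,
                               permissive = permissive)
    if (!ok) next
    g <- doc_gene_symbols(doc, gene_field)
    hits[[length(hits) + 1L]] <- data.frame(
      model = model, chrom = doc$chrom, pos = doc$pos, ref = doc$ref,
      alt = doc$alt, child_gt = tc$child$class, father_gt = tc$father$class,
      mother_gt = tc$mother$class,
      gene = if (length(g)) g[1] else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (!length(hits)) {
    return(data.frame(model = character(0), chrom = character(0),
                      pos = integer(0), ref = character(0), alt = character(0),
                      child_gt = character(0), father_gt = character(0),
                      mother_gt = character(0), gene = character(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

#' Detect compound heterozygote pairs
#'
#' For each gene, reports every unordered pair of variants at which the
#' child is heterozygous, one variant is maternal-only (mother carries it,
#' father hom-ref) and the other paternal-only. Pairs are reported once with
#' the maternal variant first; the result is invariant under the input order
#' of variants.
#'
#' @param store a `vs_store`.
#' @param pedigree data frame from [load_pedigree()].
#' @param gene_field transcript field holding the gene symbol.
#' @param min_dp,min_gq optional quality gates.
#' @param permissive treat missing genotypes as wildcards.
#' @return data frame of pairs: gene, maternal and paternal variant keys,
#'   child genotype classes at both.
#' @export
find_compound_het <- function(store, pedigree, gene_field = "SYMBOL",
                              min_dp = NULL, min_gq = NULL,
                              permissive = FALSE) {
  if (!gene_field %in% names(store$schema$fields)) {
    stop("gene field '", gene_field, "' is not in the schema")
  }
  trio <- derive_trio(pedigree)
  check_pedigree_samples(pedigree, store$schema$samples)
  cand <- list()   # per gene: list of (doc index, origin)
  docs <- store_docs(store)
  for (i in seq_along(docs)) {
    doc <- docs[[i]]
    if (is_x_contig(doc$chrom)) next
    tc <- trio_classes(doc, trio, min_dp, min_gq)
    child_het <- identical(tc$child$class, "HET") ||
      (permissive && identical(tc$child$class, "MISSING"))
    if (!child_het) next
    carrier <- function(cls) cls %in% c("HET", "HOM_ALT") ||
      (permissive && cls == "MISSING")
    homref <- function(cls) cls == "HOM_REF" ||
      (permissive && cls == "MISSING")
    maternal <- carrier(tc$mother$class) && homref(tc$father$class)
    paternal <- carrier(tc$father$class) && homref(tc$mother$class)
    if (!maternal && !paternal) next
    for (g in doc_gene_symbols(doc, gene_field)) {
      cand[[g]] <- c(cand[[g]], list(list(i = i,
        maternal = maternal && !paternal, paternal = paternal && !maternal)))
    }
  }
  pairs <- list()
  for (g in sort(names(cand))) {
    xs <- cand[[g]]
    mat <- Filter(function(x) x$maternal, xs)
    pat <- Filter(function(x) x$paternal, xs)
    for (m in mat) for (p in pat) {
      dm <- docs[[m$i]]; dp <- docs[[p$i]]
      if (variant_key_string(dm) == variant_key_string(dp)) next
      pairs[[length(pairs) + 1L]] <- data.frame(
        gene = g,
        chrom_maternal = dm$chrom, pos_maternal = dm$pos,
        ref_maternal = dm$ref, alt_maternal = dm$alt,
        chrom_paternal = dp$chrom, pos_paternal = dp$pos,
        ref_paternal = dp$ref, alt_paternal = dp$alt,
        child_gt_maternal = "HET", child_gt_paternal = "HET",
        stringsAsFactors = FALSE)
    }
  }
  if (!length(pairs)) {
    return(data.frame(gene = character(0), chrom_maternal = character(0),
                      pos_maternal = integer(0), ref_maternal = character(0),
                      alt_maternal = character(0), chrom_paternal = character(0),
                      pos_paternal = integer(0), ref_paternal = character(0),
                      alt_paternal = character(0),
                      child_gt_maternal = character(0),
                      child_gt_paternal = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, pairs)
  out[order(out$gene, out$pos_maternal, out$pos_paternal), , drop = FALSE]
}
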