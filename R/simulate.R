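#' @title Deterministic synthetic fixture generators
#' @description Generators for annotated multi-sample VCFs (VEP, Annovar or
#'   generic dialects), trio VCF+PED pairs with planted Mendelian
#'   inheritance patterns, and paired case/control cohorts. Each generator
#'   writes a machine-readable truth file sufficient to score any analysis
#'   output without re-reading the VCF. A single integer seed drives all
#'   randomness through per-component derived substreams, so identical
#'   parameters give byte-identical files. The fixtures target rule logic,
#'   not population-genetic realism (no linkage disequilibrium, uniform
#'   site-frequency choices).
#' @name fixtures
NULL

derive_seed <- function(seed, component) {
  h <- sum(utf8ToInt(component) * seq_along(utf8ToInt(component)))
  (as.integer(seed) %% 1000003L) * 1009L + (h %% 9973L)
}

BASES <- c("A", "C", "G", "T")
CONSEQUENCES <- c("missense_variant", "synonymous_variant", "intron_variant",
                  "stop_gained", "frameshift_variant", "splice_donor_variant",
                  "5_prime_UTR_variant", "downstream_gene_variant")
IMPACTS <- c("HIGH", "MODERATE", "LOW", "MODIFIER")
BIOTYPES <- c("protein_coding", "lincRNA", "retained_intron")

vcf_header_lines <- function(contigs, samples, annotation_style,
                             format_fields = c("GT", "DP", "GQ")) {
  h <- c("##fileformat=VCFv4.2",
         paste0("##contig=<ID=", contigs, ">"),
         "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alternate allele count\">",
         "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Called allele number\">",
         "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alternate allele frequency\">",
         "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP membership\">")
  if (annotation_style == "vep") {
    h <- c(h, paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=",
                     "\"Consequence annotations from Ensembl VEP. Format: ",
                     "Allele|Consequence|IMPACT|SYMBOL|Gene|BIOTYPE\">"))
  } else if (annotation_style == "annovar") {
    h <- c(h,
      "##INFO=<ID=Func.refGene,Number=1,Type=String,Description=\"Genomic context\">",
      "##INFO=<ID=Gene.refGene,Number=1,Type=String,Description=\"Gene symbol\">",
      "##INFO=<ID=ExonicFunc.refGene,Number=1,Type=String,Description=\"Exonic consequence\">",
      "##INFO=<ID=gnomAD_AF,Number=1,Type=Float,Description=\"gnomAD allele frequency\">")
  } else {
    h <- c(h,
      "##INFO=<ID=ANNO,Number=1,Type=String,Description=\"Generic annotation class\">",
      "##INFO=<ID=SCORE,Number=1,Type=Float,Description=\"Generic score\">")
  }
  fmt_desc <- c(GT = "Genotype", DP = "Read depth", GQ = "Genotype quality")
  fmt_type <- c(GT = "String", DP = "Integer", GQ = "Integer")
  for (f in format_fields) {
    h <- c(h, paste0("##FORMAT=<ID=", f, ",Number=1,Type=", fmt_type[[f]],
                     ",Description=\"", fmt_desc[[f]], "\">"))
  }
  c(h, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
               "FORMAT", samples), collapse = "\t"))
}

random_sites <- function(n, contigs) {
  chrom <- sort(factor(sample(contigs, n, replace = TRUE), levels = contigs))
  pos <- integer(n)
  for (ct in contigs) {
    idx <- which(chrom == ct)
    if (length(idx)) pos[idx] <- cumsum(sample(100:5000, length(idx), replace = TRUE))
  }
  list(chrom = as.character(chrom), pos = pos)
}

fmt_af <- function(x) sub("0+$", "", sub("\\.$", ".0", sprintf("%.6f", x)))

#' Simulate an annotated multi-sample cohort VCF
#'
#' Writes a sorted, header-consistent VCF in one of the three annotation
#' dialects plus a JSON truth file. Genotypes are drawn per sample with
#' hom-ref probability `1 - alt_fraction`; non-hom-ref draws split into het,
#' hom-alt and missing calls. AC/AN/AF INFO values are consistent with the
#' emitted genotypes. VEP style adds 1-4 CSQ transcript entries per variant.
#'
#' @param n_variants,n_samples fixture dimensions (>= 1).
#' @param annotation_style `"vep"`, `"annovar"` or `"generic"`.
#' @param alt_fraction probability that a sample call is not hom-ref.
#' @param seed integer seed; identical inputs give byte-identical files.
#' @param out_dir output directory.
#' @param multiallelic_fraction fraction of triallelic sites (default 0).
#' @param contigs contig set.
#' @return list with `vcf_path`, `truth_path`, `truth`.
#' @export
simulate_multisample_vcf <- function(n_variants, n_samples,
                                     annotation_style = "vep",
                                     alt_fraction = 0.3, seed = 1L,
                                     out_dir = tempfile("vs_fixture_"),
                                     multiallelic_fraction = 0,
                                     contigs = as.character(1:22)) {
  stopifnot(n_variants >= 1, n_samples >= 1)
  if (!(alt_fraction > 0 && alt_fraction <= 1)) {
    stop("alt_fraction must be in (0, 1]")
  }
  annotation_style <- match.arg(annotation_style, c("vep", "annovar", "generic"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(seed, "cohort"))

  samples <- sprintf("S%03d", seq_len(n_samples))
  sites <- random_sites(n_variants, contigs)
  used <- sort(unique(sites$chrom))
  lines <- character(n_variants)
  truth_variants <- vector("list", n_variants)
  total_entries <- 0L; total_docs <- 0L

  for (i in seq_len(n_variants)) {
    ref <- sample(BASES, 1)
    n_alt <- if (stats::runif(1) < multiallelic_fraction) 2L else 1L
    alts <- sample(setdiff(BASES, ref), n_alt)
    # genotype draw per sample
    gt <- character(n_samples); cls <- character(n_samples)
    allele_of <- integer(n_samples)
    for (j in seq_len(n_samples)) {
      if (stats::runif(1) >= alt_fraction) {
        gt[j] <- "0/0"; cls[j] <- "HOM_REF"; allele_of[j] <- 0L
      } else {
        kind <- sample(c("het", "hom", "missing"), 1, prob = c(0.5, 0.3, 0.2))
        a <- sample(n_alt, 1)
        sep <- sample(c("/", "|"), 1)
        if (kind == "het") {
          pair <- sample(c("0", as.character(a)))
          gt[j] <- paste(pair, collapse = sep); cls[j] <- "HET"
        } else if (kind == "hom") {
          gt[j] <- paste(a, a, sep = sep); cls[j] <- "HOM_ALT"
        } else {
          gt[j] <- paste(".", ".", sep = sep); cls[j] <- "MISSING"
        }
        allele_of[j] <- if (kind == "missing") NA_integer_ else a
      }
    }
    dp <- stats::rpois(n_samples, 35); gq <- sample(20:99, n_samples, replace = TRUE)
    n_missing <- sum(cls == "MISSING")
    an <- 2L * (n_samples - n_missing)
    ac <- vapply(seq_len(n_alt), function(a) {
      sum((cls == "HET" & allele_of == a) + 2L * (cls == "HOM_ALT" & allele_of == a),
          na.rm = TRUE)
    }, 0L)
    af <- if (an > 0) ac / an else rep(0, n_alt)
    info <- paste0("AC=", paste(ac, collapse = ","), ";AN=", an,
                   ";AF=", paste(fmt_af(af), collapse = ","))
    if (stats::runif(1) < 0.3) info <- paste0(info, ";DB")
    gene <- sprintf("GENE%04d", sample(1:200, 1))
    n_csq <- 0L
    if (annotation_style == "vep") {
      entries <- character(0)
      for (a in seq_len(n_alt)) {
        k <- sample(1:4, 1)
        for (t in seq_len(k)) {
          entries <- c(entries, paste(
            alts[a], sample(CONSEQUENCES, 1), sample(IMPACTS, 1), gene,
            sprintf("ENSG%08d", sample(1:99999, 1)), sample(BIOTYPES, 1),
            sep = "|"))
        }
      }
      n_csq <- length(entries)
      info <- paste0(info, ";CSQ=", paste(entries, collapse = ","))
    } else if (annotation_style == "annovar") {
      info <- paste0(info, ";Func.refGene=",
                     sample(c("exonic", "intronic", "UTR5", "intergenic"), 1),
                     ";Gene.refGene=", gene,
                     ";ExonicFunc.refGene=",
                     sample(c("missense", "synonymous", "stopgain"), 1),
                     ";gnomAD_AF=", fmt_af(stats::runif(1, 0, 0.2)))
    } else {
      info <- paste0(info, ";ANNO=", sample(c("classA", "classB", "classC"), 1),
                     ";SCORE=", fmt_af(stats::runif(1)))
    }
    id <- if (stats::runif(1) < 0.5) sprintf("rs%d", sample(1e4:1e7, 1)) else "."
    qual <- sprintf("%.1f", stats::runif(1, 20, 2000))
    filt <- if (stats::runif(1) < 0.9) "PASS" else "q10"
    sample_cols <- paste(gt, dp, gq, sep = ":")
    lines[i] <- paste(c(sites$chrom[i], sites$pos[i], id, ref,
                        paste(alts, collapse = ","), qual, filt, info,
                        "GT:DP:GQ", sample_cols), collapse = "\t")
    # per-allele entry accounting (every non-hom-ref call yields one entry
    # in each of the line's documents)
    n_nonref <- sum(cls != "HOM_REF")
    total_entries <- total_entries + n_alt * n_nonref
    total_docs <- total_docs + n_alt
    truth_variants[[i]] <- list(
      chrom = sites$chrom[i], pos = sites$pos[i], ref = ref,
      alts = as.list(alts), id = id, n_csq_entries = n_csq,
      n_nonref_calls = n_nonref, ac = as.list(ac), an = an,
      gt = as.list(stats::setNames(gt, samples)))
  }

  vcf_path <- file.path(out_dir, "cohort.vcf")
  writeLines(c(vcf_header_lines(used, samples, annotation_style), lines),
             vcf_path)
  truth <- list(generator = "simulate_multisample_vcf", seed = seed,
                params = list(n_variants = n_variants, n_samples = n_samples,
                              annotation_style = annotation_style,
                              alt_fraction = alt_fraction,
                              multiallelic_fraction = multiallelic_fraction),
                n_data_lines = n_variants, n_documents = total_docs,
                total_sample_entries = total_entries,
                variants = truth_variants)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(vcf_path = vcf_path, truth_path = truth_path, truth = truth)
}

trio_plant_genotypes <- function(model, child_is_male, on_x) {
  # returns c(child, father, mother) GT strings; male X calls are haploid
  if (!on_x) {
    switch(model,
      autosomal_de_novo = c("0/1", "0/0", "0/0"),
      autosomal_dominant = c("0/1", "0/1", "0/0"),
      autosomal_recessive = c("1/1", "0/1", "0/1"),
      stop("model ", model, " is not autosomal"))
  } else {
    child_alt <- if (child_is_male) "1" else "0/1"
    switch(model,
      x_linked_de_novo = c(child_alt, "0", "0/0"),
      x_linked_dominant = c(child_alt, "0", "0/1"),
      x_linked_recessive = c(if (child_is_male) "1" else
        stop("x_linked_recessive plants require a male child"), "0", "0/1"),
      stop("model ", model, " is not X-linked"))
  }
}

trio_background_genotypes <- function(child_is_male, on_x) {
  # patterns that satisfy none of the seven rule tables
  pat <- sample(c("child_homref", "all_het", "all_homalt"), 1,
                prob = c(0.6, 0.25, 0.15))
  male <- function(g) if (on_x) substr(g, 1, 1) else g   # haploid male X
  if (on_x) {
    # X background keeps the child non-carrier
    fa <- male(sample(c("0/0", "1/1"), 1))
    mo <- sample(c("0/0", "0/1"), 1)
    ch <- if (child_is_male) "0" else "0/0"
    return(c(ch, fa, mo))
  }
  switch(pat,
    child_homref = c("0/0", sample(c("0/0", "0/1", "1/1"), 1),
                     sample(c("0/0", "0/1", "1/1"), 1)),
    all_het = c("0/1", "0/1", "0/1"),
    all_homalt = c("1/1", "1/1", "1/1"))
}

#' Simulate a trio VCF + PED pair with planted inheritance patterns
#'
#' Background variants satisfy none of the seven models; each planted
#' variant satisfies exactly its model's rule table (compound-het counts are
#' pairs sharing a gene). The PED encodes an affected child; the father is
#' additionally affected when autosomal-dominant plants are requested and
#' the mother when X-linked-dominant plants are requested. The child is male
#' when X-linked-recessive plants are requested, female otherwise. Male X
#' genotypes are written haploid to exercise hemizygous normalization.
#'
#' @param n_background number of background variants (autosomes).
#' @param planted named list/vector, model name -> count (pairs for
#'   `compound_heterozygous`).
#' @param seed integer seed.
#' @param out_dir output directory.
#' @param father_affected,mother_affected explicit parent statuses; `NULL`
#'   derives them from the planted models; a contradiction (e.g. dominant
#'   plants with both parents forced unaffected) errors.
#' @return list with `vcf_path`, `ped_path`, `truth_path`, `truth`.
#' @export
simulate_trio <- function(n_background = 2000L, planted = list(), seed = 1L,
                          out_dir = tempfile("vs_trio_"),
                          father_affected = NULL, mother_affected = NULL) {
  planted <- as.list(planted)
  bad <- setdiff(names(planted), MENDELIAN_MODELS)
  if (length(bad)) stop("unknown model(s): ", paste(bad, collapse = ", "))
  counts <- vapply(MENDELIAN_MODELS, function(m)
    as.integer(planted[[m]] %||% 0L), 0L)
  names(counts) <- MENDELIAN_MODELS
  if (any(counts < 0)) stop("planted counts must be >= 0")

  fa_aff <- father_affected %||% (counts[["autosomal_dominant"]] > 0)
  mo_aff <- mother_affected %||% (counts[["x_linked_dominant"]] > 0)
  if (counts[["autosomal_dominant"]] > 0 && !fa_aff && !mo_aff) {
    stop("autosomal_dominant plants require an affected parent")
  }
  if (counts[["autosomal_dominant"]] > 0 && !fa_aff) {
    stop("autosomal_dominant plants are placed on the father; set father_affected = TRUE")
  }
  if (counts[["x_linked_dominant"]] > 0 && !mo_aff) {
    stop("x_linked_dominant plants are placed on the mother; set mother_affected = TRUE")
  }
  if (counts[["autosomal_dominant"]] > 0 && counts[["x_linked_dominant"]] > 0) {
    stop("autosomal_dominant and x_linked_dominant plants need contradictory ",
         "parent statuses; generate them in separate fixtures")
  }
  child_is_male <- counts[["x_linked_recessive"]] > 0
  need_x <- any(counts[c("x_linked_de_novo", "x_linked_dominant",
                         "x_linked_recessive")] > 0)

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(seed, "trio"))
  samples <- c("CHILD01", "FATHER01", "MOTHER01")

  n_chet_sites <- 2L * counts[["compound_heterozygous"]]
  auto_models <- c(rep("autosomal_de_novo", counts[["autosomal_de_novo"]]),
                   rep("autosomal_dominant", counts[["autosomal_dominant"]]),
                   rep("autosomal_recessive", counts[["autosomal_recessive"]]))
  x_models <- c(rep("x_linked_de_novo", counts[["x_linked_de_novo"]]),
                rep("x_linked_dominant", counts[["x_linked_dominant"]]),
                rep("x_linked_recessive", counts[["x_linked_recessive"]]))
  n_auto <- n_background + length(auto_models) + n_chet_sites
  n_x_background <- if (need_x) 50L else 0L
  n_x <- n_x_background + length(x_models)

  auto_sites <- random_sites(n_auto, as.character(1:22))
  # which autosomal slots hold plants
  slot <- rep("none", n_auto)
  plant_slots <- sample(n_auto, length(auto_models) + n_chet_sites)
  if (length(auto_models)) {
    slot[plant_slots[seq_along(auto_models)]] <- auto_models
  }
  chet_slots <- plant_slots[length(auto_models) + seq_len(n_chet_sites)]
  if (n_chet_sites) slot[chet_slots] <- "compound_heterozygous"
  chet_gene_of <- integer(0)
  chet_role_of <- character(0)
  if (n_chet_sites) {
    ord <- order(chet_slots)
    chet_gene_of <- stats::setNames(rep(seq_len(counts[["compound_heterozygous"]]),
                                        each = 2), chet_slots[ord])
    chet_role_of <- stats::setNames(rep(c("maternal", "paternal"),
                                        counts[["compound_heterozygous"]]),
                                    chet_slots[ord])
  }

  x_sites <- if (n_x) {
    pos <- cumsum(sample(100:5000, n_x, replace = TRUE))
    x_slot <- rep("none", n_x)
    xp <- sample(n_x, length(x_models))
    x_slot[xp] <- x_models
    list(pos = pos, slot = x_slot)
  } else NULL

  lines <- character(0)
  truth_rows <- list()
  emit <- function(chrom, pos, model, gts, gene) {
    ref <- sample(BASES, 1); alt <- sample(setdiff(BASES, ref), 1)
    csq <- paste(alt, sample(CONSEQUENCES, 1), sample(IMPACTS, 1), gene,
                 sprintf("ENSG%08d", sample(1:99999, 1)),
                 "protein_coding", sep = "|")
    dp <- sample(30:60, 3, replace = TRUE); gq <- sample(60:99, 3, replace = TRUE)
    n_missing <- sum(grepl("\\.", gts))
    ac <- sum(vapply(strsplit(gts, "[/|]"), function(a) sum(a == "1"), 0L))
    an <- 2L * (3L - n_missing)
    info <- paste0("AC=", ac, ";AN=", an, ";AF=", fmt_af(ac / max(an, 1L)),
                   ";CSQ=", csq)
    line <- paste(c(chrom, pos, ".", ref, alt, "100.0", "PASS", info,
                    "GT:DP:GQ", paste(gts, dp, gq, sep = ":")),
                  collapse = "\t")
    lines[[length(lines) + 1L]] <<- line
    truth_rows[[length(truth_rows) + 1L]] <<- list(
      chrom = chrom, pos = pos, ref = ref, alt = alt, model = model,
      gene = gene, child_gt = gts[1], father_gt = gts[2], mother_gt = gts[3])
  }

  for (i in seq_len(n_auto)) {
    m <- slot[i]
    if (m == "none") {
      gts <- trio_background_genotypes(child_is_male, on_x = FALSE)
      gene <- sprintf("BG%05d", i)
      emit(auto_sites$chrom[i], auto_sites$pos[i], "none", gts, gene)
    } else if (m == "compound_heterozygous") {
      role <- chet_role_of[[as.character(i)]]
      gene <- sprintf("CHGENE%02d", chet_gene_of[[as.character(i)]])
      gts <- if (role == "maternal") c("0/1", "0/0", "0/1") else c("0/1", "0/1", "0/0")
      emit(auto_sites$chrom[i], auto_sites$pos[i],
           paste0("compound_heterozygous_", role), gts, gene)
    } else {
      gts <- trio_plant_genotypes(m, child_is_male, on_x = FALSE)
      emit(auto_sites$chrom[i], auto_sites$pos[i], m, gts,
           sprintf("PL%05d", i))
    }
  }
  if (n_x) {
    for (i in seq_len(n_x)) {
      m <- x_sites$slot[i]
      gts <- if (m == "none") {
        trio_background_genotypes(child_is_male, on_x = TRUE)
      } else {
        trio_plant_genotypes(m, child_is_male, on_x = TRUE)
      }
      if (child_is_male) {
        # ensure haploid child calls on X
      }
      emit("X", x_sites$pos[i], if (m == "none") "none" else m, gts,
           sprintf("XG%05d", i))
    }
  }

  contigs <- c(as.character(1:22), if (n_x) "X")
  vcf_path <- file.path(out_dir, "trio.vcf")
  writeLines(c(vcf_header_lines(contigs, samples, "vep"), unlist(lines)),
             vcf_path)

  ped_path <- file.path(out_dir, "trio.ped")
  writeLines(c(
    paste("FAM01", "CHILD01", "FATHER01", "MOTHER01",
          if (child_is_male) 1 else 2, 2),
    paste("FAM01", "FATHER01", "0", "0", 1, if (fa_aff) 2 else 1),
    paste("FAM01", "MOTHER01", "0", "0", 2, if (mo_aff) 2 else 1)),
    ped_path)

  truth <- list(generator = "simulate_trio", seed = seed,
                params = list(n_background = n_background,
                              planted = as.list(counts),
                              child_sex = if (child_is_male) "male" else "female",
                              father_affected = fa_aff,
                              mother_affected = mo_aff),
                variants = truth_rows)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(vcf_path = vcf_path, ped_path = ped_path, truth_path = truth_path,
       truth = truth)
}

#' Simulate paired case/control cohort VCFs
#'
#' Both cohorts share one biallelic site list; allele frequencies are equal
#' in expectation except at `delta_sites` sites, where the case frequency is
#' shifted by `delta`. Genotypes are drawn under Hardy-Weinberg sampling
#' with no missing calls, and the truth file records the exact realized
#' allele counts per cohort.
#'
#' @param n_variants shared site count.
#' @param n_case,n_control cohort sizes.
#' @param delta_sites number of sites with a planted frequency difference.
#' @param delta planted frequency shift (in [0, 1]).
#' @param seed integer seed.
#' @param out_dir output directory.
#' @return list with `case_vcf`, `control_vcf`, `truth_path`, `truth`.
#' @export
simulate_case_control <- function(n_variants = 500L, n_case = 100L,
                                  n_control = 100L, delta_sites = 20L,
                                  delta = 0.2, seed = 1L,
                                  out_dir = tempfile("vs_cc_")) {
  stopifnot(delta >= 0, delta <= 1, delta_sites <= n_variants)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(derive_seed(seed, "casecontrol"))

  sites <- random_sites(n_variants, as.character(1:22))
  base_af <- stats::runif(n_variants, 0.05, 0.5)
  which_delta <- if (delta_sites > 0) sort(sample(n_variants, delta_sites)) else integer(0)
  case_af <- base_af
  case_af[which_delta] <- pmin(base_af[which_delta] + delta, 0.95)

  ref <- sample(BASES, n_variants, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(BASES, r), 1), "")

  draw_cohort <- function(af, n_samples) {
    # one genotype matrix row per site; entries are alt-allele dosages 0/1/2
    matrix(stats::rbinom(n_variants * n_samples, 2, rep(af, n_samples)),
           nrow = n_variants)
  }
  case_gt <- draw_cohort(case_af, n_case)
  ctrl_gt <- draw_cohort(base_af, n_control)

  gt_string <- function(d) c("0/0", "0/1", "1/1")[d + 1L]
  write_cohort <- function(gt, ids, path) {
    body <- vapply(seq_len(n_variants), function(i) {
      dos <- gt[i, ]
      ac <- sum(dos); an <- 2L * length(dos)
      info <- paste0("AC=", ac, ";AN=", an, ";AF=", fmt_af(ac / an),
                     ";ANNO=shared;SCORE=", fmt_af(base_af[i]))
      paste(c(sites$chrom[i], sites$pos[i], ".", ref[i], alt[i], "50.0",
              "PASS", info, "GT", gt_string(dos)), collapse = "\t")
    }, "")
    writeLines(c(vcf_header_lines(sort(unique(sites$chrom)), ids, "generic",
                                  format_fields = "GT"), body), path)
  }
  case_ids <- sprintf("CASE%03d", seq_len(n_case))
  ctrl_ids <- sprintf("CTRL%03d", seq_len(n_control))
  case_vcf <- file.path(out_dir, "case.vcf")
  control_vcf <- file.path(out_dir, "control.vcf")
  write_cohort(case_gt, case_ids, case_vcf)
  write_cohort(ctrl_gt, ctrl_ids, control_vcf)

  truth_variants <- lapply(seq_len(n_variants), function(i) {
    ca_alt <- sum(case_gt[i, ]); co_alt <- sum(ctrl_gt[i, ])
    list(chrom = sites$chrom[i], pos = sites$pos[i], ref = ref[i],
         alt = alt[i], is_delta_site = i %in% which_delta,
         planted_case_af = case_af[i], planted_control_af = base_af[i],
         case_alt_alleles = ca_alt, case_called_alleles = 2L * n_case,
         case_af = ca_alt / (2 * n_case),
         control_alt_alleles = co_alt,
         control_called_alleles = 2L * n_control,
         control_af = co_alt / (2 * n_control))
  })
  truth <- list(generator = "simulate_case_control", seed = seed,
                params = list(n_variants = n_variants, n_case = n_case,
                              n_control = n_control, delta_sites = delta_sites,
                              delta = delta),
                variants = truth_variants)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(case_vcf = case_vcf, control_vcf = control_vcf,
       truth_path = truth_path, truth = truth)
}
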