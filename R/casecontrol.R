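#' @title Case/control allele-distribution comparison
#' @description Matches a case-cohort store against a control-cohort VCF on
#'   the decomposed variant key (chrom, pos, ref, alt) and reports per-site
#'   alternate-allele counts and frequencies in both cohorts. A variant
#'   absent from one cohort is counted as hom-ref across that cohort's
#'   samples (a convention, surfaced via `present_in`).
#' @name casecontrol
NULL

#' Alternate-allele distribution of one variant in a cohort
#'
#' Alt-allele dosage per stored entry is 1 for het, 2 for hom-alt, and the
#' recorded number of matching alt alleles for other calls; missing entries
#' remove a sample's two alleles from the called total; absent samples count
#' as hom-ref (0 alt alleles, 2 called).
#'
#' @param sample_entries the document's sparse genotype entries.
#' @param n_cohort_samples total samples in the cohort.
#' @return list `alt_alleles`, `called_alleles`, `af`.
#' @export
allele_distribution <- function(sample_entries, n_cohort_samples) {
  if (n_cohort_samples < length(sample_entries)) {
    stop("n_cohort_samples (", n_cohort_samples,
         ") is less than the number of genotype entries (",
         length(sample_entries), ")")
  }
  alt <- 0L; n_missing <- 0L
  for (e in sample_entries) {
    if (identical(e$gt_class, "MISSING")) { n_missing <- n_missing + 1L; next }
    d <- switch(e$gt_class,
      HET = 1L, HOM_ALT = 2L,
      {  # OTHER: use the recorded per-allele dosage
        ac <- e$alt_copies
        if (is.null(ac) || is.na(ac)) 0L else as.integer(ac)
      })
    alt <- alt + d
  }
  called <- 2L * (n_cohort_samples - n_missing)
  list(alt_alleles = alt, called_alleles = called,
       af = if (called > 0) alt / called else 0)
}

check_sorted_docs <- function(docs, label) {
  last_chrom <- NULL; last_pos <- -Inf; seen <- character(0)
  for (d in docs) {
    if (!identical(d$chrom, last_chrom)) {
      if (d$chrom %in% seen) {
        stop(label, " is not position-sorted (contig ", d$chrom,
             " appears in two blocks)")
      }
      seen <- c(seen, d$chrom)
      last_chrom <- d$chrom; last_pos <- -Inf
    }
    if (d$pos < last_pos) {
      stop(label, " is not position-sorted at ", d$chrom, ":", d$pos)
    }
    last_pos <- d$pos
  }
  invisible(TRUE)
}

#' Match case and control cohorts on the decomposed variant key
#'
#' Every key present in either cohort yields exactly one pair; matching
#' requires chrom, pos, ref and alt all equal. The control VCF must be
#' position-sorted.
#'
#' @param case_store a `vs_store` holding the case cohort.
#' @param control_vcf_path annotated, sorted VCF of the control cohort.
#' @return list with `pairs` (list of `list(case=, control=)`, either side
#'   possibly `NULL`), `n_control_samples`, and the control schema.
#' @export
match_cohorts <- function(case_store, control_vcf_path) {
  ctrl_schema <- infer_schema(control_vcf_path)
  if (!length(ctrl_schema$samples)) {
    stop("control VCF declares no samples")
  }
  ctrl_store <- create_index(ctrl_schema, persist = FALSE)
  ingest_vcf(control_vcf_path, ctrl_store)
  ctrl_docs <- store_docs(ctrl_store)
  check_sorted_docs(ctrl_docs, "control VCF")

  ctrl_by_key <- new.env(parent = emptyenv())
  for (d in ctrl_docs) assign(variant_key_string(d), d, envir = ctrl_by_key)

  pairs <- list(); seen <- new.env(parent = emptyenv())
  for (d in store_docs(case_store)) {
    key <- variant_key_string(d)
    ctrl <- if (exists(key, envir = ctrl_by_key)) get(key, envir = ctrl_by_key) else NULL
    pairs[[length(pairs) + 1L]] <- list(case = d, control = ctrl)
    assign(key, TRUE, envir = seen)
  }
  for (d in ctrl_docs) {
    key <- variant_key_string(d)
    if (!exists(key, envir = seen)) {
      pairs[[length(pairs) + 1L]] <- list(case = NULL, control = d)
    }
  }
  list(pairs = pairs, n_control_samples = length(ctrl_schema$samples),
       control_schema = ctrl_schema)
}

#' Compare allele distributions between a case store and a control VCF
#'
#' One record per matched key passing the (case-schema-validated) filters;
#' counts and frequencies per cohort, with the absence-as-hom-ref convention
#' flagged in `present_in`. An optional two-sided Fisher exact test on the
#' 2x2 allele-count table can be attached per record.
#'
#' @param case_store a `vs_store`.
#' @param control_vcf path to the control cohort VCF.
#' @param filters optional list of [filter_spec()] applied to the case
#'   documents (a record present only in the control cohort passes when no
#'   filters are given).
#' @param fisher attach `p_fisher` per record.
#' @return data frame of case/control records.
#' @export
compare_case_control <- function(case_store, control_vcf, filters = list(),
                                 fisher = FALSE) {
  cq <- NULL
  if (length(filters)) {
    cq <- validate_query(vs_query(attributes = "CHROM", filters = filters),
                         case_store$schema)
  }
  mc <- match_cohorts(case_store, control_vcf)
  n_case <- length(case_store$schema$samples)
  n_ctrl <- mc$n_control_samples
  if (n_case == 0) stop("case store declares no samples")
  recs <- list()
  for (pr in mc$pairs) {
    if (!is.null(cq)) {
      ref_doc <- pr$case %||% pr$control
      if (!is.null(pr$case) && !doc_matches(pr$case, cq)) next
      if (is.null(pr$case)) next   # filters are case-schema scoped
    }
    d <- pr$case %||% pr$control
    ca <- if (!is.null(pr$case)) {
      allele_distribution(pr$case$sample_entries, n_case)
    } else list(alt_alleles = 0L, called_alleles = 2L * n_case, af = 0)
    co <- if (!is.null(pr$control)) {
      allele_distribution(pr$control$sample_entries, n_ctrl)
    } else list(alt_alleles = 0L, called_alleles = 2L * n_ctrl, af = 0)
    rec <- data.frame(
      chrom = d$chrom, pos = d$pos, ref = d$ref, alt = d$alt,
      case_alt_alleles = ca$alt_alleles, case_called_alleles = ca$called_alleles,
      case_af = ca$af,
      control_alt_alleles = co$alt_alleles,
      control_called_alleles = co$called_alleles, control_af = co$af,
      present_in = if (is.null(pr$control)) "case_only"
        else if (is.null(pr$case)) "control_only" else "both",
      stringsAsFactors = FALSE)
    if (fisher) {
      m <- matrix(c(ca$alt_alleles, ca$called_alleles - ca$alt_alleles,
                    co$alt_alleles, co$called_alleles - co$alt_alleles),
                  nrow = 2)
      rec$p_fisher <- stats::fisher.test(m)$p.value
    }
    recs[[length(recs) + 1L]] <- rec
  }
  if (!length(recs)) {
    cols <- c("chrom", "pos", "ref", "alt", "case_alt_alleles",
              "case_called_alleles", "case_af", "control_alt_alleles",
              "control_called_alleles", "control_af", "present_in")
    out <- stats::setNames(
      as.data.frame(rep(list(character(0)), length(cols))), cols)
    return(out)
  }
  do.call(rbind, recs)
}
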