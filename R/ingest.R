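#' @title Annotated VCF ingestion
#' @description Turns data lines of an annotated multi-sample VCF into
#'   variant documents: one document per ALT allele, with flat INFO
#'   attributes, nested per-transcript CSQ annotations, and sparse per-sample
#'   genotype entries (hom-ref calls are represented by absence).
#' @name ingest
NULL

GT_CLASSES <- c("HOM_REF", "HET", "HOM_ALT", "MISSING", "OTHER")

#' Classify a raw GT string
#'
#' `0/0` and `0|0` are hom-ref; one reference and one non-reference allele is
#' het; two identical non-reference alleles is hom-alt; any `.` allele is
#' missing; everything else (haploid calls, two different alt alleles,
#' polyploid calls) is `OTHER`. The phasing separator never changes the
#' class.
#'
#' @param gt_raw a GT string such as `"0|1"`.
#' @return one of `"HOM_REF"`, `"HET"`, `"HOM_ALT"`, `"MISSING"`, `"OTHER"`.
#' @export
classify_genotype <- function(gt_raw) {
  if (!is.character(gt_raw) || length(gt_raw) != 1 || !nzchar(gt_raw)) {
    stop("gt_raw must be a single non-empty GT string")
  }
  al <- strsplit(gt_raw, "[/|]")[[1]]
  if (any(al == ".")) return("MISSING")
  if (length(al) != 2) return("OTHER")
  if (al[1] == "0" && al[2] == "0") return("HOM_REF")
  nz <- al != "0"
  if (sum(nz) == 1) return("HET")
  if (al[1] == al[2]) return("HOM_ALT")
  "OTHER"
}

# Classify a GT string with respect to one decomposed ALT allele
# (allele_index is the 1-based index of that ALT in the original line).
classify_genotype_allele <- function(gt_raw, allele_index) {
  al <- strsplit(gt_raw, "[/|]")[[1]]
  if (!length(al) || any(al == ".")) {
    if (any(al == ".")) return(list(class = "MISSING", alt_copies = NA_integer_))
    stop("empty GT string")
  }
  idx <- as.character(allele_index)
  n_target <- sum(al == idx)
  cls <- if (length(al) != 2) "OTHER"
    else if (al[1] == "0" && al[2] == "0") "HOM_REF"
    else if (n_target == 2) "HOM_ALT"
    else if (n_target == 1 && any(al == "0")) "HET"
    else "OTHER"
  list(class = cls, alt_copies = as.integer(n_target))
}

# Split a raw INFO string into a named character vector (flags get "").
split_info_string <- function(info_string) {
  if (info_string == "." || !nzchar(info_string)) {
    return(stats::setNames(character(0), character(0)))
  }
  toks <- strsplit(info_string, ";", fixed = TRUE)[[1]]
  keys <- character(length(toks)); vals <- character(length(toks))
  for (i in seq_along(toks)) {
    eq <- regexpr("=", toks[i], fixed = TRUE)
    if (eq == 1L) {
      stop("malformed INFO pair '", toks[i], "': empty key")
    }
    if (eq > 0) {
      keys[i] <- substr(toks[i], 1, eq - 1)
      vals[i] <- substr(toks[i], eq + 1, nchar(toks[i]))
    } else {
      keys[i] <- toks[i]
      vals[i] <- NA_character_   # bare flag
    }
  }
  stats::setNames(vals, keys)
}

type_info_value <- function(value, spec) {
  if (is.null(spec)) {
    num <- suppressWarnings(as.numeric(value))
    return(if (!is.na(num)) num else value)
  }
  switch(spec$data_type,
    integer = {
      v <- suppressWarnings(as.integer(value))
      if (is.na(v)) value else v
    },
    float = {
      v <- suppressWarnings(as.numeric(value))
      if (is.na(v)) value else v
    },
    flag = TRUE,
    value)
}

#' Parse a VCF INFO column into typed attribute-value pairs
#'
#' `key=value` tokens become typed entries (per the schema's declared or
#' inferred types), bare keys become flag entries with value `TRUE`, and the
#' CSQ key is never included here — it is routed to [parse_csq_block()].
#'
#' @param info_string the raw INFO column (or `"."`).
#' @param schema optional `vs_schema` used for value typing.
#' @return a named list of attribute values.
#' @export
parse_info_pairs <- function(info_string, schema = NULL) {
  kv <- split_info_string(info_string)
  kv <- kv[names(kv) != "CSQ"]
  out <- vector("list", length(kv))
  names(out) <- names(kv)
  for (i in seq_along(kv)) {
    key <- names(kv)[i]
    spec <- if (!is.null(schema)) schema$fields[[key]] else NULL
    out[[i]] <- if (is.na(kv[[i]])) TRUE else type_info_value(kv[[i]], spec)
  }
  out
}

#' Parse a CSQ annotation block into per-transcript annotations
#'
#' The CSQ INFO value is a comma-separated list of transcript annotations;
#' within each, pipe-separated values are matched positionally to the format
#' declared in the VCF header. Empty positions are omitted from the result.
#'
#' @param csq_value the raw CSQ value string.
#' @param csq_format ordered field names from the header's CSQ description.
#' @return a list with one named list per transcript annotation.
#' @export
parse_csq_block <- function(csq_value, csq_format) {
  stopifnot(length(csq_format) >= 1)
  entries <- strsplit(csq_value, ",", fixed = TRUE)[[1]]
  lapply(seq_along(entries), function(i) {
    fv <- strsplit(entries[i], "|", fixed = TRUE)[[1]]
    if (length(fv) > length(csq_format)) {
      stop("CSQ entry ", i, " has ", length(fv),
           " fields but the declared format has ", length(csq_format))
    }
    keep <- nchar(fv) > 0
    stats::setNames(as.list(fv[keep]), csq_format[seq_along(fv)][keep])
  })
}

type_csq_values <- function(ann, schema) {
  # rename raw CSQ names to schema names (collision-safe) and type values
  if (!length(ann)) return(ann)
  raw <- schema$csq_format
  mapped <- schema$csq_names
  out <- list()
  for (nm in names(ann)) {
    i <- match(nm, raw)
    snm <- if (!is.na(i)) mapped[i] else nm
    spec <- schema$fields[[snm]]
    v <- ann[[nm]]
    if (!is.null(spec) && spec$data_type %in% c("integer", "float")) {
      nv <- suppressWarnings(as.numeric(v))
      if (!is.na(nv)) v <- nv
    }
    out[[snm]] <- v
  }
  out
}

#' Parse FORMAT/sample columns into sparse genotype entries
#'
#' Entries are produced only for samples whose genotype class is not hom-ref;
#' missing (`./.`) calls ARE stored, so that absence of an entry
#' unambiguously means hom-ref.
#'
#' @param format_keys FORMAT column split into keys (e.g. `c("GT","DP")`).
#' @param sample_columns raw per-sample strings.
#' @param sample_ids sample names (same length as `sample_columns`).
#' @param allele_index 1-based ALT allele index used for genotype
#'   classification (1 for biallelic sites).
#' @return a list of genotype entries (`sample_id`, `gt_raw`, `gt_class`,
#'   `alt_copies`, `format_values`).
#' @export
parse_sample_entries <- function(format_keys, sample_columns, sample_ids,
                                 allele_index = 1L) {
  stopifnot(length(sample_columns) == length(sample_ids))
  gi <- match("GT", format_keys)
  out <- list()
  for (j in seq_along(sample_columns)) {
    fv <- strsplit(sample_columns[j], ":", fixed = TRUE)[[1]]
    if (length(fv) != length(format_keys)) {
      stop("sample ", sample_ids[j], ": ", length(fv),
           " FORMAT values for ", length(format_keys), " keys")
    }
    gt <- if (!is.na(gi)) fv[gi] else "."
    cl <- classify_genotype_allele(gt, allele_index)
    if (cl$class == "HOM_REF") next
    vals <- list()
    for (k in seq_along(format_keys)) {
      if (!is.na(gi) && k == gi) next
      v <- fv[k]
      if (v == "." || !nzchar(v)) next
      nv <- suppressWarnings(as.numeric(v))
      vals[[format_keys[k]]] <- if (!is.na(nv)) nv else v
    }
    out[[length(out) + 1L]] <- list(
      sample_id = sample_ids[j], gt_raw = gt, gt_class = cl$class,
      alt_copies = cl$alt_copies, format_values = vals)
  }
  out
}

#' Decompose one VCF data line into per-ALT variant documents
#'
#' Multi-allelic sites yield one document per ALT allele. CSQ annotations are
#' assigned to the document whose ALT matches the annotation's `Allele` field
#' (to all documents when the annotation has no `Allele` field or it matches
#' no ALT); `Number=A` INFO values are split positionally; sample genotype
#' classes are computed against each document's allele. Monomorphic lines
#' (`ALT="."`) are skipped with a warning recorded by the caller.
#'
#' @param vcf_data_line one tab-separated VCF data line.
#' @param schema a `vs_schema` from [infer_schema()].
#' @param source_line 1-based index of the line among the file's data lines.
#' @return a list of variant documents (possibly empty).
#' @export
decompose_record <- function(vcf_data_line, schema, source_line = 1L) {
  f <- strsplit(vcf_data_line, "\t", fixed = TRUE)[[1]]
  if (length(f) < 8) stop("data line ", source_line, ": fewer than 8 columns")
  alts <- strsplit(f[5], ",", fixed = TRUE)[[1]]
  if (length(alts) == 0 || identical(f[5], ".")) {
    return(structure(list(), monomorphic = TRUE))
  }
  kv <- split_info_string(f[8])
  csq_raw <- if ("CSQ" %in% names(kv)) kv[["CSQ"]] else NULL
  flat_raw <- kv[names(kv) != "CSQ"]
  qual <- if (f[6] == ".") NULL else as.numeric(f[6])
  dbsnp <- if (f[3] == ".") NULL else f[3]
  format_keys <- if (length(f) >= 9) strsplit(f[9], ":", fixed = TRUE)[[1]] else character(0)
  sample_cols <- if (length(f) >= 10) f[10:length(f)] else character(0)

  anns <- if (!is.null(csq_raw) && length(schema$csq_format)) {
    lapply(parse_csq_block(csq_raw, schema$csq_format), type_csq_values,
           schema = schema)
  } else list()
  allele_name <- if (length(schema$csq_format)) {
    i <- match("Allele", schema$csq_format)
    if (!is.na(i)) schema$csq_names[i] else NA_character_
  } else NA_character_

  docs <- vector("list", length(alts))
  for (ai in seq_along(alts)) {
    flat <- list()
    for (key in names(flat_raw)) {
      v <- flat_raw[[key]]
      spec <- schema$fields[[key]]
      if (is.na(v)) { flat[[key]] <- TRUE; next }
      num_decl <- schema$info_number[key]
      if (!is.na(num_decl) && identical(unname(num_decl), "A")) {
        parts <- strsplit(v, ",", fixed = TRUE)[[1]]
        v <- if (ai <= length(parts)) parts[ai] else NA_character_
        if (is.na(v)) next
      }
      flat[[key]] <- type_info_value(v, spec)
    }
    my_anns <- anns
    if (length(anns) && !is.na(allele_name)) {
      alleles <- vapply(anns, function(a) a[[allele_name]] %||% NA_character_, "")
      has_match <- alleles %in% alts
      my_anns <- anns[(alleles == alts[ai]) | !has_match]
    }
    entries <- if (length(sample_cols)) {
      parse_sample_entries(format_keys, sample_cols, schema$samples, ai)
    } else list()
    doc <- list(chrom = f[1], pos = as.integer(f[2]), ref = f[4],
                alt = alts[ai], qual = qual, filter_status = f[7],
                dbsnp_id = dbsnp, flat_attributes = flat,
                transcript_annotations = my_anns, sample_entries = entries,
                flag = NULL, source_line = as.integer(source_line))
    docs[[ai]] <- doc
  }
  docs
}

#' Plan balanced line-range chunks over a VCF's data lines
#'
#' Chunks are contiguous, disjoint, cover every data line exactly once, and
#' differ in size by at most one line, so each can be parsed independently by
#' one worker.
#'
#' @param vcf_path path to the VCF.
#' @param n_workers number of parallel workers (>= 1).
#' @return a list of chunks (`source`, `first_data_line` 0-based, `n_lines`).
#' @export
plan_chunks <- function(vcf_path, n_workers) {
  stopifnot(n_workers >= 1)
  lines <- read_vcf_lines(vcf_path)
  n <- sum(!startsWith(lines, "#"))
  if (n == 0) {
    warning("VCF has no data lines; empty chunk plan")
    return(list())
  }
  k <- as.integer(min(n_workers, n))
  base <- n %/% k; extra <- n %% k
  sizes <- rep(base, k) + c(rep(1L, extra), rep(0L, k - extra))
  starts <- cumsum(c(0L, sizes[-k]))
  lapply(seq_len(k), function(i) {
    list(source = vcf_path, first_data_line = starts[i], n_lines = sizes[i])
  })
}

parse_chunk_lines <- function(lines, schema, first_index) {
  n_warn <- 0L
  per_line <- lapply(seq_along(lines), function(i) {
    d <- decompose_record(lines[i], schema, source_line = first_index + i - 1L)
    if (isTRUE(attr(d, "monomorphic"))) {
      n_warn <<- n_warn + 1L
      return(list())
    }
    d
  })
  list(docs = do.call(c, per_line), n_monomorphic = n_warn)
}

#' Ingest an annotated VCF into a document store
#'
#' The file's data lines are split into balanced chunks, each parsed into
#' variant documents (in parallel when `n_workers > 1`, via forked
#' processes), and bulk-loaded into the store in chunk order, so the stored
#' document multiset is independent of `n_workers`.
#'
#' @param vcf_path path to the annotated VCF.
#' @param store a store created by [create_index()].
#' @param n_workers number of parallel parser workers.
#' @return an ingest report (`n_data_lines`, `n_documents`, `n_chunks`,
#'   `per_chunk_document_counts`, `warnings`).
#' @export
ingest_vcf <- function(vcf_path, store, n_workers = 1L) {
  schema <- store$schema
  lines <- read_vcf_lines(vcf_path)
  data_lines <- lines[!startsWith(lines, "#")]
  n <- length(data_lines)
  if (n == 0) {
    return(list(n_data_lines = 0L, n_documents = 0L, n_chunks = 0L,
                per_chunk_document_counts = integer(0),
                warnings = "no data lines"))
  }
  plan <- plan_chunks(vcf_path, n_workers)
  work <- function(ch) {
    idx <- seq.int(ch$first_data_line + 1L, ch$first_data_line + ch$n_lines)
    parse_chunk_lines(data_lines[idx], schema, first_index = ch$first_data_line + 1L)
  }
  results <- if (n_workers > 1L && .Platform$OS.type == "unix") {
    out <- parallel::mclapply(plan, work, mc.cores = n_workers)
    bad <- vapply(out, inherits, TRUE, "try-error")
    if (any(bad)) stop("chunk worker ", which(bad)[1], " failed: ",
                       as.character(out[[which(bad)[1]]]))
    out
  } else {
    lapply(plan, work)
  }
  counts <- integer(length(results))
  warnings <- character(0)
  for (i in seq_along(results)) {
    counts[i] <- length(results[[i]]$docs)
    if (results[[i]]$n_monomorphic > 0) {
      warnings <- c(warnings, sprintf("chunk %d: %d monomorphic line(s) skipped",
                                      i, results[[i]]$n_monomorphic))
    }
    bulk_load(store, results[[i]]$docs)
  }
  list(n_data_lines = n, n_documents = sum(counts),
       n_chunks = length(results), per_chunk_document_counts = counts,
       warnings = warnings)
}

variant_key_string <- function(doc) {
  paste(doc$chrom, doc$pos, doc$ref, doc$alt, sep = ":")
}
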