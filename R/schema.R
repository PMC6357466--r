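#' @title Annotation schema inference
#' @description Internal machinery that reads a VCF header plus a sample of
#'   data lines and produces an `vs_schema` object: one field spec per
#'   queryable attribute (core column, flat INFO key, nested CSQ transcript
#'   field, or per-sample FORMAT field), with an inferred data type, display
#'   group and filter widget.
#' @name schema
NULL

VS_GROUP_VARIANT <- "Variant Related Information"
VS_GROUP_SAMPLE  <- "Sample Related Information"

#' Construct a single annotation field specification
#'
#' @param name field name, unique within a schema.
#' @param source one of `core`, `info_flat`, `csq_nested`, `sample_format`.
#' @param data_type one of `integer`, `float`, `categorical`, `text`, `flag`.
#' @param cardinality number of distinct observed values (0 when unobserved).
#' @param group display-group label.
#' @param widget filter widget; derived from `data_type` when `NULL`
#'   (numeric -> `range`, categorical -> `dropdown`, flag -> `checkbox`,
#'   text -> `text_search`).
#' @param values sorted observed values (dropdown options) for categorical
#'   fields.
#' @param number VCF `Number=` declaration (`"A"` triggers per-allele
#'   splitting during record decomposition).
#' @return a list of class `vs_field_spec`.
#' @export
field_spec <- function(name, source, data_type, cardinality = 0L,
                       group = VS_GROUP_VARIANT, widget = NULL,
                       values = NULL, number = NULL) {
  stopifnot(is.character(name), nchar(name) > 0)
  source <- match.arg(source, c("core", "info_flat", "csq_nested", "sample_format"))
  data_type <- match.arg(data_type, c("integer", "float", "categorical", "text", "flag"))
  if (is.null(widget)) {
    widget <- switch(data_type,
      integer = "range", float = "range",
      categorical = "dropdown", flag = "checkbox", text = "text_search")
  }
  structure(list(name = name, source = source, data_type = data_type,
                 cardinality = as.integer(cardinality), group = group,
                 widget = widget, values = values, number = number),
            class = "vs_field_spec")
}

new_schema <- function(fields, csq_format = character(0), samples = character(0),
                       annotation_style = "generic") {
  nm <- vapply(fields, `[[`, "", "name")
  if (anyDuplicated(nm)) {
    stop("duplicate field name(s) in schema: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  }
  names(fields) <- nm
  if (annotation_style == "vep" && length(csq_format) == 0) {
    stop("annotation_style 'vep' requires a non-empty CSQ format")
  }
  if (annotation_style != "vep" && length(csq_format) > 0) {
    stop("csq_format must be empty unless annotation_style is 'vep'")
  }
  structure(list(fields = fields, csq_format = csq_format, samples = samples,
                 annotation_style = annotation_style),
            class = "vs_schema")
}

#' @export
print.vs_schema <- function(x, ...) {
  cat("<vs_schema> style=", x$annotation_style,
      " fields=", length(x$fields),
      " samples=", length(x$samples),
      if (length(x$csq_format)) paste0(" csq=", length(x$csq_format)) else "",
      "\n", sep = "")
  invisible(x)
}

schema_field <- function(schema, name) {
  sp <- schema$fields[[name]]
  if (is.null(sp)) stop("unknown field: ", name)
  sp
}

field_scope <- function(spec) {
  switch(spec$source,
    core = "variant", info_flat = "variant",
    csq_nested = "transcript", sample_format = "sample")
}

# --- header parsing -----------------------------------------------------

# Parse one ##INFO=<...> / ##FORMAT=<...> structured header line into its
# key=value components (ID, Number, Type, Description).
parse_header_meta <- function(line) {
  inner <- sub("^##[A-Za-z]+=<", "", sub(">\\s*$", "", line))
  out <- list(); key <- ""; val <- ""; in_val <- FALSE; in_q <- FALSE
  chars <- strsplit(inner, "", fixed = TRUE)[[1]]
  for (ch in chars) {
    if (in_q) {
      if (ch == "\"") in_q <- FALSE else val <- paste0(val, ch)
    } else if (ch == "\"") {
      in_q <- TRUE
    } else if (ch == "=" && !in_val) {
      in_val <- TRUE
    } else if (ch == "," && in_val) {
      out[[key]] <- val; key <- ""; val <- ""; in_val <- FALSE
    } else if (in_val) {
      val <- paste0(val, ch)
    } else {
      key <- paste0(key, ch)
    }
  }
  if (nchar(key)) out[[key]] <- val
  out
}

read_vcf_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

split_vcf_lines <- function(lines) {
  is_header <- startsWith(lines, "#")
  # header must be a contiguous prefix
  body_at <- which(!is_header)
  list(header = lines[is_header], data = lines[!is_header])
}

parse_vcf_header <- function(header_lines) {
  chrom_line <- grep("^#CHROM\t", header_lines, value = TRUE)
  if (length(chrom_line) != 1) stop("VCF header is missing the #CHROM line")
  cols <- strsplit(chrom_line, "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else character(0)

  info_meta <- list(); format_meta <- list(); csq_format <- character(0)
  for (ln in header_lines) {
    if (startsWith(ln, "##INFO=<")) {
      m <- parse_header_meta(ln)
      info_meta[[m$ID]] <- m
      if (identical(m$ID, "CSQ") && !is.null(m$Description)) {
        fmt <- sub(".*Format:\\s*", "", m$Description)
        csq_format <- strsplit(fmt, "|", fixed = TRUE)[[1]]
      }
    } else if (startsWith(ln, "##FORMAT=<")) {
      m <- parse_header_meta(ln)
      format_meta[[m$ID]] <- m
    }
  }
  list(samples = samples, info_meta = info_meta, format_meta = format_meta,
       csq_format = csq_format)
}

# --- type inference helpers --------------------------------------------

looks_numeric <- function(v) {
  v <- v[nchar(v) > 0]
  if (!length(v)) return(FALSE)
  suppressWarnings(!anyNA(as.numeric(v)))
}

looks_integer <- function(v) {
  v <- v[nchar(v) > 0]
  all(grepl("^-?[0-9]+$", v))
}

observed_type <- function(vals, dropdown_threshold) {
  vals <- unique(vals[!is.na(vals) & nchar(vals) > 0])
  if (!length(vals)) return(list(data_type = "text", values = NULL, cardinality = 0L))
  if (looks_numeric(vals)) {
    dt <- if (looks_integer(vals)) "integer" else "float"
    return(list(data_type = dt, values = NULL, cardinality = length(vals)))
  }
  if (length(vals) <= dropdown_threshold) {
    return(list(data_type = "categorical", values = sort(vals),
                cardinality = length(vals)))
  }
  list(data_type = "text", values = NULL, cardinality = length(vals))
}

header_declared_type <- function(meta) {
  switch(meta$Type,
    Integer = "integer", Float = "float", Flag = "flag",
    String = NA_character_, Character = NA_character_,
    NA_character_)
}

#' Infer an annotation schema from a VCF header and a record sample
#'
#' Field data types come from the header `Type=` declarations where present;
#' string-typed and CSQ transcript fields fall back to the observed values in
#' the first `k` records (all-numeric values give a numeric range field;
#' up to `dropdown_threshold` distinct strings give a categorical dropdown;
#' anything else is free-text). Core columns, INFO attributes and CSQ fields
#' are grouped under "Variant Related Information", FORMAT fields under
#' "Sample Related Information". A header declaration that conflicts with the
#' observed values wins, with a warning.
#'
#' @param vcf_path path to a (optionally gzip-compressed) VCF 4.x file.
#' @param k number of data lines sampled for observed-value inference.
#' @param dropdown_threshold a string field with at most this many distinct
#'   observed values becomes categorical.
#' @param annotation_style `"auto"` (VEP when a CSQ INFO key is declared, else
#'   generic), or one of `"vep"`, `"annovar"`, `"generic"`.
#' @return a `vs_schema` object.
#' @export
infer_schema <- function(vcf_path, k = 5000L, dropdown_threshold = 50L,
                         annotation_style = "auto") {
  stopifnot(k >= 1)
  lines <- read_vcf_lines(vcf_path)
  parts <- split_vcf_lines(lines)
  hdr <- parse_vcf_header(parts$header)
  sample_lines <- utils::head(parts$data, k)

  has_csq <- "CSQ" %in% names(hdr$info_meta) && length(hdr$csq_format) > 0
  if (annotation_style == "auto") {
    annotation_style <- if (has_csq) "vep" else "generic"
  }
  if (annotation_style == "vep" && !has_csq) {
    stop("annotation_style 'vep' but the header declares no CSQ format")
  }

  tab <- strsplit(sample_lines, "\t", fixed = TRUE)

  # observed values per column of interest
  obs_chrom <- unique(vapply(tab, `[[`, "", 1))
  obs_filter <- unique(vapply(tab, function(x) x[7], ""))

  fields <- list()
  add <- function(sp) fields[[length(fields) + 1L]] <<- sp

  add(field_spec("CHROM", "core", "categorical",
                 cardinality = length(obs_chrom), values = sort(obs_chrom)))
  add(field_spec("POS", "core", "integer"))
  add(field_spec("REF", "core", "text"))
  add(field_spec("ALT", "core", "text"))
  add(field_spec("QUAL", "core", "float"))
  add(field_spec("FILTER", "core", "categorical",
                 cardinality = length(obs_filter), values = sort(obs_filter)))
  add(field_spec("dbsnp_id", "core", "text", widget = "excluded_toggle"))
  add(field_spec("flag", "core", "categorical", cardinality = 2L,
                 values = c("Approved", "Rejected")))

  # observed INFO values (for string-typed INFO keys)
  info_obs <- new.env(parent = emptyenv())
  for (x in tab) {
    if (length(x) < 8 || x[8] == ".") next
    for (tok in strsplit(x[8], ";", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", tok, fixed = TRUE)
      if (eq > 0) {
        key <- substr(tok, 1, eq - 1)
        if (key == "CSQ") next
        val <- substr(tok, eq + 1, nchar(tok))
        info_obs[[key]] <- c(info_obs[[key]],
                             strsplit(val, ",", fixed = TRUE)[[1]])
      }
    }
  }

  for (id in names(hdr$info_meta)) {
    if (id == "CSQ") next
    meta <- hdr$info_meta[[id]]
    declared <- header_declared_type(meta)
    vals <- unique(info_obs[[id]])
    if (identical(meta$Number, "0") || identical(declared, "flag")) {
      add(field_spec(id, "info_flat", "flag", number = meta$Number))
      next
    }
    if (!is.na(declared)) {
      if (length(vals) && !looks_numeric(vals)) {
        warning("INFO field ", id, " declared ", meta$Type,
                " but has non-numeric values; keeping header declaration")
      }
      add(field_spec(id, "info_flat", declared, cardinality = length(vals),
                     number = meta$Number))
    } else {
      ot <- observed_type(vals, dropdown_threshold)
      add(field_spec(id, "info_flat", ot$data_type, cardinality = ot$cardinality,
                     values = ot$values, number = meta$Number))
    }
  }

  csq_format <- character(0)
  if (annotation_style == "vep") {
    csq_format <- hdr$csq_format
    csq_obs <- lapply(seq_along(csq_format), function(i) character(0))
    for (x in tab) {
      if (length(x) < 8) next
      m <- regmatches(x[8], regexpr("(?:^|;)CSQ=[^;]*", x[8]))
      if (!length(m)) next
      val <- sub("^;?CSQ=", "", m)
      for (entry in strsplit(val, ",", fixed = TRUE)[[1]]) {
        fv <- strsplit(entry, "|", fixed = TRUE)[[1]]
        for (i in seq_along(fv)) {
          if (i <= length(csq_obs) && nchar(fv[i]) > 0) {
            csq_obs[[i]] <- c(csq_obs[[i]], fv[i])
          }
        }
      }
    }
    for (i in seq_along(csq_format)) {
      nm <- csq_format[i]
      if (nm %in% vapply(fields, `[[`, "", "name")) nm <- paste0(nm, "_csq")
      ot <- observed_type(unique(csq_obs[[i]]), dropdown_threshold)
      add(field_spec(nm, "csq_nested", ot$data_type,
                     cardinality = ot$cardinality, values = ot$values))
    }
    csq_format_names <- vapply(
      fields[vapply(fields, function(f) f$source == "csq_nested", TRUE)],
      `[[`, "", "name")
  }

  # sample-scoped pseudo-fields + FORMAT fields
  if (length(hdr$samples)) {
    add(field_spec("Sample_ID", "sample_format", "categorical",
                   cardinality = length(hdr$samples), group = VS_GROUP_SAMPLE,
                   values = sort(hdr$samples)))
    gt_obs <- character(0)
    for (x in tab) {
      if (length(x) < 10) next
      fk <- strsplit(x[9], ":", fixed = TRUE)[[1]]
      gi <- match("GT", fk)
      if (is.na(gi)) next
      gts <- vapply(x[10:length(x)],
                    function(s) strsplit(s, ":", fixed = TRUE)[[1]][gi], "")
      gt_obs <- unique(c(gt_obs, gts))
    }
    for (id in names(hdr$format_meta)) {
      meta <- hdr$format_meta[[id]]
      nm <- id
      existing <- vapply(fields, `[[`, "", "name")
      if (nm %in% existing) nm <- paste0(nm, "_sample")
      if (id == "GT") {
        add(field_spec(nm, "sample_format", "categorical",
                       cardinality = length(gt_obs), group = VS_GROUP_SAMPLE,
                       values = sort(gt_obs)))
        next
      }
      declared <- header_declared_type(meta)
      dt <- if (is.na(declared)) "text" else declared
      if (dt %in% c("integer", "float") && !is.null(meta$Number) &&
          !meta$Number %in% c("1", "A", "0")) {
        dt <- "text"
        warning("FORMAT field ", id, " has Number=", meta$Number,
                "; stored as text")
      }
      add(field_spec(nm, "sample_format", dt, group = VS_GROUP_SAMPLE,
                     number = meta$Number))
    }
  }

  sch <- new_schema(fields, csq_format = csq_format, samples = hdr$samples,
                    annotation_style = annotation_style)
  # map from raw VCF names to schema names where a collision forced a rename
  sch$csq_names <- if (annotation_style == "vep") {
    vapply(sch$fields[vapply(sch$fields, function(f) f$source == "csq_nested", TRUE)],
           `[[`, "", "name")
  } else character(0)
  sch$format_ids <- names(hdr$format_meta)
  sch$format_names <- vapply(hdr$format_meta, function(m) {
    nm <- m$ID
    nm
  }, "")
  sch$info_number <- vapply(hdr$info_meta, function(m) {
    if (is.null(m$Number)) "." else m$Number
  }, "")
  sch
}

schema_to_list <- function(schema) {
  list(
    fields = lapply(unname(schema$fields), function(f) {
      f[!vapply(f, is.null, TRUE)]
    }),
    csq_format = as.list(schema$csq_format),
    samples = as.list(schema$samples),
    annotation_style = schema$annotation_style,
    csq_names = as.list(schema$csq_names),
    info_number = as.list(schema$info_number)
  )
}

schema_from_list <- function(x) {
  fields <- lapply(x$fields, function(f) {
    field_spec(f$name, f$source, f$data_type,
               cardinality = if (is.null(f$cardinality)) 0L else f$cardinality,
               group = f$group, widget = f$widget,
               values = if (is.null(f$values)) NULL else unlist(f$values),
               number = f$number)
  })
  sch <- new_schema(fields, csq_format = unlist(x$csq_format) %||% character(0),
                    samples = unlist(x$samples) %||% character(0),
                    annotation_style = x$annotation_style)
  sch$csq_names <- unlist(x$csq_names) %||% character(0)
  sch$info_number <- unlist(x$info_number) %||% character(0)
  sch
}

`%||%` <- function(a, b) if (is.null(a)) b else a
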