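#' @title Scoped filter query engine
#' @description Compiles and executes include/exclude filters over the three
#'   scopes of a variant document — variant-level attributes, nested
#'   transcript annotations, nested sample genotype entries — with attribute
#'   projection, a display cap, CSV export, a saved-query registry,
#'   review flags, and external-resource links.
#' @name query
NULL

VS_OPERATORS <- c("eq", "in", "lt", "le", "gt", "ge", "exists", "not_exists")
VS_DISPLAY_CAP <- 400L

#' Construct a filter specification
#'
#' @param field schema field name.
#' @param operator one of `eq`, `in`, `lt`, `le`, `gt`, `ge`, `exists`,
#'   `not_exists`.
#' @param values filter value(s); required for all operators except
#'   `exists` / `not_exists`.
#' @param polarity `"include"` (variant must satisfy it) or `"exclude"`
#'   (variant must not satisfy it).
#' @return a `vs_filter` list.
#' @export
filter_spec <- function(field, operator, values = NULL, polarity = "include") {
  operator <- match.arg(operator, VS_OPERATORS)
  polarity <- match.arg(polarity, c("include", "exclude"))
  structure(list(field = field, operator = operator,
                 values = values, polarity = polarity),
            class = "vs_filter")
}

#' Construct a query
#'
#' Filters combine conjunctively; disjunction is expressed through
#' multi-value `in` filters. Attributes are projected in the given order.
#'
#' @param attributes ordered character vector of schema field names.
#' @param filters list of [filter_spec()] objects.
#' @param dataset dataset label.
#' @param analysis_type `"exploration"`, `"case_control"`, or
#'   `"mendelian:<model>"`.
#' @return a `vs_query` list.
#' @export
vs_query <- function(attributes, filters = list(), dataset = "default",
                     analysis_type = "exploration") {
  structure(list(dataset = dataset, analysis_type = analysis_type,
                 filters = filters, attributes = attributes),
            class = "vs_query")
}

#' Validate a query against a schema and compile it
#'
#' Checks that every filter field exists, that its scope matches the field's
#' source, that range operators are applied to numeric fields only, and that
#' the attribute list is non-empty and schema-resolvable; range values are
#' parsed to numbers.
#'
#' @param query a `vs_query`.
#' @param schema a `vs_schema`.
#' @return a compiled query (`vs_compiled_query`).
#' @export
validate_query <- function(query, schema) {
  stopifnot(inherits(query, "vs_query"))
  if (!length(query$attributes)) stop("attribute list is empty")
  for (a in query$attributes) {
    if (is.null(schema$fields[[a]])) stop("unknown attribute: ", a)
  }
  filters <- lapply(query$filters, function(fl) {
    spec <- schema$fields[[fl$field]]
    if (is.null(spec)) stop("unknown filter field: ", fl$field)
    numeric_field <- spec$data_type %in% c("integer", "float")
    if (fl$operator %in% c("lt", "le", "gt", "ge") && !numeric_field) {
      stop("operator '", fl$operator, "' requires a numeric field, but '",
           fl$field, "' is ", spec$data_type)
    }
    if (fl$operator == "in" && length(fl$values) < 1) {
      stop("operator 'in' on '", fl$field, "' requires at least one value")
    }
    if (!fl$operator %in% c("exists", "not_exists")) {
      if (is.null(fl$values) || !length(fl$values)) {
        stop("operator '", fl$operator, "' on '", fl$field, "' requires a value")
      }
    }
    vals <- fl$values
    if (numeric_field && !is.null(vals)) {
      vals <- suppressWarnings(as.numeric(vals))
      if (anyNA(vals)) stop("non-numeric value for numeric field '", fl$field, "'")
    }
    list(field = fl$field, scope = field_scope(spec), operator = fl$operator,
         values = vals, polarity = fl$polarity, numeric = numeric_field)
  })
  attrs <- lapply(query$attributes, function(a) {
    list(name = a, scope = field_scope(schema$fields[[a]]))
  })
  inc <- Filter(function(f) f$polarity == "include", filters)
  structure(list(query = query, filters = filters, attributes = attrs,
                 inc_v = Filter(function(f) f$scope == "variant", inc),
                 inc_t = Filter(function(f) f$scope == "transcript", inc),
                 inc_s = Filter(function(f) f$scope == "sample", inc),
                 exc = Filter(function(f) f$polarity == "exclude", filters)),
            class = "vs_compiled_query")
}

# --- value extraction ---------------------------------------------------

variant_value <- function(doc, name) {
  switch(name,
    CHROM = doc$chrom, POS = doc$pos, REF = doc$ref, ALT = doc$alt,
    QUAL = doc$qual, FILTER = doc$filter_status,
    dbsnp_id = doc$dbsnp_id, flag = doc$flag,
    doc$flat_attributes[[name]])
}

transcript_value <- function(entry, name) entry[[name]]

sample_value <- function(entry, name) {
  switch(name,
    Sample_ID = entry$sample_id,
    GT = entry$gt_raw,
    entry$format_values[[name]])
}

predicate <- function(value, flt) {
  op <- flt$operator
  if (op == "exists") return(!is.null(value))
  if (op == "not_exists") return(is.null(value))
  if (is.null(value)) return(FALSE)
  if (flt$numeric) {
    v <- suppressWarnings(as.numeric(value))
    if (is.na(v)) return(FALSE)
    switch(op,
      eq = v %in% flt$values,
      `in` = v %in% flt$values,
      lt = v < flt$values[1], le = v <= flt$values[1],
      gt = v > flt$values[1], ge = v >= flt$values[1])
  } else {
    v <- as.character(value)
    switch(op,
      eq = v %in% as.character(flt$values),
      `in` = v %in% as.character(flt$values),
      FALSE)
  }
}

# A single filter holds on a document: variant scope tests the flat value;
# nested scopes test whether ANY entry satisfies it.
filter_holds <- function(doc, flt) {
  switch(flt$scope,
    variant = predicate(variant_value(doc, flt$field), flt),
    transcript = any(vapply(doc$transcript_annotations, function(tr)
      predicate(transcript_value(tr, flt$field), flt), TRUE)),
    sample = any(vapply(doc$sample_entries, function(se)
      predicate(sample_value(se, flt$field), flt), TRUE)))
}

# Joint same-entry match: entries satisfying ALL given filters at once.
matching_entries <- function(entries, filters, getter) {
  if (!length(filters)) return(seq_along(entries))
  which(vapply(entries, function(e)
    all(vapply(filters, function(fl) predicate(getter(e, fl$field), fl), TRUE)),
    TRUE))
}

doc_matches <- function(doc, cq) {
  for (fl in cq$inc_v) if (!filter_holds(doc, fl)) return(FALSE)
  if (length(cq$inc_t) &&
      !length(matching_entries(doc$transcript_annotations, cq$inc_t,
                               transcript_value))) return(FALSE)
  if (length(cq$inc_s) &&
      !length(matching_entries(doc$sample_entries, cq$inc_s,
                               sample_value))) return(FALSE)
  for (fl in cq$exc) if (isTRUE(filter_holds(doc, fl))) return(FALSE)
  TRUE
}

project_rows <- function(doc, cq) {
  inc_t <- cq$inc_t
  inc_s <- cq$inc_s
  scopes <- vapply(cq$attributes, `[[`, "", "scope")
  want_t <- any(scopes == "transcript")
  want_s <- any(scopes == "sample")
  tr_idx <- if (want_t) {
    ix <- matching_entries(doc$transcript_annotations, inc_t, transcript_value)
    if (!length(ix)) NA_integer_ else ix
  } else NA_integer_
  se_idx <- if (want_s) {
    ix <- matching_entries(doc$sample_entries, inc_s, sample_value)
    if (!length(ix)) NA_integer_ else ix
  } else NA_integer_
  rows <- list()
  for (ti in tr_idx) for (si in se_idx) {
    row <- lapply(cq$attributes, function(a) {
      v <- switch(a$scope,
        variant = variant_value(doc, a$name),
        transcript = if (is.na(ti)) NULL
          else transcript_value(doc$transcript_annotations[[ti]], a$name),
        sample = if (is.na(si)) NULL
          else sample_value(doc$sample_entries[[si]], a$name))
      if (is.null(v)) NA else v
    })
    rows[[length(rows) + 1L]] <- row
  }
  rows
}

rows_to_df <- function(rows, attr_names) {
  if (!length(rows)) {
    df <- as.data.frame(stats::setNames(rep(list(character(0)), length(attr_names)),
                                        attr_names),
                        check.names = FALSE, stringsAsFactors = FALSE)
    return(df)
  }
  cols <- lapply(seq_along(attr_names), function(j) {
    vals <- lapply(rows, `[[`, j)
    if (all(vapply(vals, function(v) is.numeric(v) || (length(v) == 1 && is.na(v)), TRUE))) {
      vapply(vals, function(v) if (length(v) == 1 && is.na(v)) NA_real_ else as.numeric(v), 0)
    } else {
      vapply(vals, function(v) if (length(v) == 1 && is.na(v)) NA_character_ else as.character(v), "")
    }
  })
  stats::setNames(as.data.frame(cols, check.names = FALSE,
                                stringsAsFactors = FALSE), attr_names)
}

#' Execute a compiled query against a store
#'
#' A variant matches when all include filters are satisfied and no exclude
#' filter is satisfied; transcript- and sample-scoped include filters use
#' same-entry semantics (one nested entry must satisfy all of them jointly).
#' When a nested attribute is selected the result has one row per variant x
#' matching nested entry; display mode truncates the rows at the display cap
#' in store (source line) order, full mode returns everything.
#'
#' @param cq a `vs_compiled_query` from [validate_query()].
#' @param store a `vs_store`.
#' @param mode `"display"` or `"full"`.
#' @param display_cap row cap for display mode (default 400).
#' @return list with `rows` (data frame), `total_matched` (full row count)
#'   and `truncated`.
#' @export
execute <- function(cq, store, mode = c("display", "full"),
                    display_cap = VS_DISPLAY_CAP) {
  if (!inherits(cq, "vs_compiled_query")) {
    stop("query must be validated with validate_query() before execution")
  }
  mode <- match.arg(mode)
  attr_names <- vapply(cq$attributes, `[[`, "", "name")
  rows <- list()
  for (doc in store_docs(store)) {
    if (!doc_matches(doc, cq)) next
    rows <- c(rows, project_rows(doc, cq))
  }
  total <- length(rows)
  truncated <- (mode == "display") && total > display_cap
  if (truncated) rows <- rows[seq_len(display_cap)]
  list(rows = rows_to_df(rows, attr_names), total_matched = total,
       truncated = truncated)
}

#' Export the full result set of a query to CSV
#'
#' Writes all matching rows (no display cap) with a header row of the
#' attribute names in query order, RFC-4180 quoting, UTF-8.
#'
#' @param cq a compiled query.
#' @param store a `vs_store`.
#' @param path output file path.
#' @return the number of data rows written.
#' @export
export_csv <- function(cq, store, path) {
  res <- execute(cq, store, mode = "full")
  ok <- FALSE
  tryCatch({
    utils::write.csv(res$rows, path, row.names = FALSE, fileEncoding = "UTF-8",
                     quote = which(vapply(res$rows, is.character, TRUE)))
    ok <- TRUE
  }, error = function(e) {
    if (file.exists(path)) unlink(path)
    stop("CSV export failed: ", conditionMessage(e))
  })
  nrow(res$rows)
}

# --- saved queries ------------------------------------------------------

query_to_list <- function(query) {
  list(dataset = query$dataset, analysis_type = query$analysis_type,
       filters = lapply(query$filters, function(fl)
         list(field = fl$field, operator = fl$operator,
              values = as.list(fl$values), polarity = fl$polarity)),
       attributes = as.list(query$attributes))
}

query_from_list <- function(x) {
  vs_query(attributes = unlist(x$attributes),
           filters = lapply(x$filters, function(fl)
             filter_spec(fl$field, fl$operator,
                         values = if (length(fl$values)) unlist(fl$values) else NULL,
                         polarity = fl$polarity)),
           dataset = x$dataset, analysis_type = x$analysis_type)
}

read_registry <- function(registry_path) {
  if (!file.exists(registry_path)) return(list())
  jsonlite::read_json(registry_path)
}

#' Save a query under a name in a local registry file
#'
#' @param name registry key (non-empty).
#' @param query a `vs_query`.
#' @param registry_path JSON registry file.
#' @param overwrite allow replacing an existing entry.
#' @return the saved entry (name, query, created timestamp), invisibly.
#' @export
save_query <- function(name, query, registry_path, overwrite = FALSE) {
  stopifnot(nchar(name) > 0, inherits(query, "vs_query"))
  reg <- read_registry(registry_path)
  if (!is.null(reg[[name]]) && !overwrite) {
    stop("a query named '", name, "' already exists (use overwrite = TRUE)")
  }
  entry <- list(name = name, query = query_to_list(query),
                created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  reg[[name]] <- entry
  jsonlite::write_json(reg, registry_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(entry)
}

#' Recall a saved query by name
#'
#' @param name registry key.
#' @param registry_path JSON registry file.
#' @return the saved `vs_query`.
#' @export
recall_query <- function(name, registry_path) {
  reg <- read_registry(registry_path)
  if (is.null(reg[[name]])) stop("no saved query named '", name, "'")
  query_from_list(reg[[name]]$query)
}

# --- review flags -------------------------------------------------------

#' Flag a variant as Approved or Rejected (or clear the flag)
#'
#' The flag is persisted in the index directory and applied to all
#' subsequent query results, so an exclude filter on `flag = Rejected`
#' removes rejected variants.
#'
#' @param store a `vs_store`.
#' @param chrom,pos,ref,alt the variant key.
#' @param flag `"Approved"`, `"Rejected"`, or `"clear"`.
#' @return the updated document, invisibly.
#' @export
set_flag <- function(store, chrom, pos, ref, alt, flag) {
  flag <- match.arg(flag, c("Approved", "Rejected", "clear"))
  key <- paste(chrom, pos, ref, alt, sep = ":")
  hit <- NULL
  for (d in store$docs) {
    if (variant_key_string(d) == key) { hit <- d; break }
  }
  if (is.null(hit)) stop("no variant with key ", key, " in the store")
  if (flag == "clear") {
    store$flags[[key]] <- NULL
  } else {
    store$flags[[key]] <- flag
    hit$flag <- flag
  }
  if (isTRUE(store$persist)) {
    jsonlite::write_json(
      if (length(store$flags)) store$flags else stats::setNames(list(), character(0)),
      file.path(store$dir, "flags.json"), auto_unbox = TRUE)
  }
  invisible(hit)
}

# --- external links -----------------------------------------------------

default_link_templates <- function() {
  list(
    ucsc = "https://genome.ucsc.edu/cgi-bin/hgTracks?db=hg19&position=chr{chrom}:{start}-{end}",
    decipher = "https://www.deciphergenomics.org/search?q={chrom}:{pos}",
    genemania = "https://genemania.org/search/homo-sapiens/{genes}"
  )
}

#' Build external-resource URLs for one variant document
#'
#' Produces deterministic links to the UCSC genome browser (a window around
#' the position), DECIPHER (the position), and GeneMANIA (the gene symbols
#' found in the document's transcript annotations; omitted when there are
#' none).
#'
#' @param doc a variant document.
#' @param templates named list of URL templates (placeholders `{chrom}`,
#'   `{pos}`, `{start}`, `{end}`, `{genes}`).
#' @param window half-width of the UCSC window in bp.
#' @param gene_field transcript field holding the gene symbol.
#' @return named list of URLs.
#' @export
build_external_links <- function(doc, templates = default_link_templates(),
                                 window = 500L, gene_field = "SYMBOL") {
  chrom <- sub("^chr", "", doc$chrom)
  fill <- function(t) {
    t <- gsub("{chrom}", chrom, t, fixed = TRUE)
    t <- gsub("{pos}", as.character(doc$pos), t, fixed = TRUE)
    t <- gsub("{start}", as.character(max(1L, doc$pos - window)), t, fixed = TRUE)
    gsub("{end}", as.character(doc$pos + window), t, fixed = TRUE)
  }
  out <- list(ucsc = fill(templates$ucsc), decipher = fill(templates$decipher))
  genes <- unique(unlist(lapply(doc$transcript_annotations, `[[`, gene_field)))
  genes <- genes[!is.na(genes) & nchar(genes) > 0]
  if (length(genes)) {
    out$genemania <- gsub("{genes}", paste(sort(genes), collapse = "|"),
                          templates$genemania, fixed = TRUE)
  }
  out
}
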