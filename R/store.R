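#' @title Embedded variant document store
#' @description Reference backend for the store contract: create an index
#'   from a schema (field mapping + UI config), bulk-load documents in
#'   batches, scan with nested-scope filter semantics, persist everything as
#'   structured text under one index directory (mapping.json, schema.json,
#'   uiconfig.json, documents.ndjson, flags.json).
#' @name store
NULL

#' Create a document index from an annotation schema
#'
#' Builds the per-field storage mapping (numeric fields support range
#' retrieval; categorical/text/flag fields support term retrieval; CSQ and
#' FORMAT fields live inside the `transcript_annotations` and
#' `sample_entries` nested blocks with same-entry conjunction semantics),
#' writes the mapping, schema and UI-config artifacts, and returns an empty
#' store handle.
#'
#' @param schema a `vs_schema`.
#' @param index_dir directory for the index artifacts (created if needed).
#' @param persist write documents to disk on load (default `TRUE`).
#' @return a `vs_store` handle.
#' @export
create_index <- function(schema, index_dir = tempfile("vs_index_"),
                         persist = TRUE) {
  mapping <- build_field_mapping(schema)
  ui <- generate_ui_config(schema)
  dir.create(index_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(schema_to_list(schema), file.path(index_dir, "schema.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(mapping, file.path(index_dir, "mapping.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(ui, file.path(index_dir, "uiconfig.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  file.create(file.path(index_dir, "documents.ndjson"))
  jsonlite::write_json(stats::setNames(list(), character(0)),
                       file.path(index_dir, "flags.json"), auto_unbox = TRUE)
  st <- new.env(parent = emptyenv())
  st$dir <- index_dir
  st$schema <- schema
  st$mapping <- mapping
  st$docs <- list()
  st$flags <- list()
  st$persist <- persist
  class(st) <- "vs_store"
  st
}

build_field_mapping <- function(schema) {
  entries <- list()
  for (f in schema$fields) {
    kind <- if (f$data_type %in% c("integer", "float")) "numeric" else "keyword"
    block <- switch(f$source,
      csq_nested = "transcript_annotations",
      sample_format = "sample_entries",
      NA_character_)
    e <- list(name = f$name, kind = kind)
    if (!is.na(block)) e$nested_block <- block
    if (f$name %in% names(entries)) stop("duplicate field name: ", f$name)
    entries[[f$name]] <- e
  }
  list(fields = unname(entries),
       nested_blocks = c("transcript_annotations", "sample_entries"))
}

#' Generate the UI configuration artifact from a schema
#'
#' Panels come in a fixed order — "Variant Related Information" (core + flat
#' INFO fields), a transcript-annotation panel for VEP-style schemas, then
#' "Sample Related Information" (FORMAT fields; omitted when there are
#' none). Each panel lists `(field, widget, options)` with dropdown options
#' equal to the sorted observed categorical values; optional identifier
#' fields (dbsnp_id) get an excluded toggle. The output is deterministic for
#' a given schema.
#'
#' @param schema a `vs_schema`.
#' @return a list of panels.
#' @export
generate_ui_config <- function(schema) {
  entry <- function(f) {
    e <- list(field = f$name, widget = f$widget)
    if (f$widget == "dropdown" && !is.null(f$values)) {
      e$options <- as.list(sort(f$values))
    }
    e
  }
  src <- vapply(schema$fields, `[[`, "", "source")
  panels <- list(list(
    label = VS_GROUP_VARIANT,
    fields = lapply(unname(schema$fields[src %in% c("core", "info_flat")]), entry)))
  if (any(src == "csq_nested")) {
    panels[[length(panels) + 1L]] <- list(
      label = "Transcript Annotations",
      fields = lapply(unname(schema$fields[src == "csq_nested"]), entry))
  }
  if (any(src == "sample_format")) {
    panels[[length(panels) + 1L]] <- list(
      label = VS_GROUP_SAMPLE,
      fields = lapply(unname(schema$fields[src == "sample_format"]), entry))
  }
  list(panels = panels)
}

validate_document <- function(doc, schema) {
  for (nm in names(doc$flat_attributes)) {
    if (is.null(schema$fields[[nm]])) {
      stop("document at source line ", doc$source_line,
           " has unmapped attribute '", nm, "'")
    }
  }
  sids <- vapply(doc$sample_entries, `[[`, "", "sample_id")
  if (anyDuplicated(sids)) {
    stop("document at source line ", doc$source_line, " has duplicate sample entries")
  }
  if (length(sids) && !all(sids %in% schema$samples)) {
    stop("document at source line ", doc$source_line,
         " has sample ids outside the header sample list")
  }
  invisible(TRUE)
}

doc_to_json <- function(doc) {
  doc <- doc[!vapply(doc, is.null, TRUE)]
  if (!is.null(doc$flat_attributes) && length(doc$flat_attributes) == 0) {
    doc$flat_attributes <- NULL
  }
  as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA))
}

#' Bulk-load documents into a store
#'
#' Documents are validated against the index mapping and appended in batches;
#' query results do not depend on load order beyond the documents' own
#' `source_line` ordering used for display.
#'
#' @param store a `vs_store`.
#' @param documents list of variant documents.
#' @param batch_size documents per persisted batch (default 512).
#' @return the number of documents loaded.
#' @export
bulk_load <- function(store, documents, batch_size = 512L) {
  stopifnot(inherits(store, "vs_store"), batch_size >= 1)
  if (!length(documents)) return(0L)
  for (d in documents) validate_document(d, store$schema)
  if (store$persist) {
    con <- file(file.path(store$dir, "documents.ndjson"), open = "a")
    on.exit(close(con))
    i <- 1L
    while (i <= length(documents)) {
      j <- min(i + batch_size - 1L, length(documents))
      writeLines(vapply(documents[i:j], doc_to_json, ""), con)
      i <- j + 1L
    }
  }
  store$docs <- c(store$docs, documents)
  length(documents)
}

#' Reopen a persisted index directory
#'
#' @param index_dir directory previously populated by [create_index()].
#' @return a `vs_store` handle with documents and flags loaded.
#' @export
open_store <- function(index_dir) {
  schema <- schema_from_list(
    jsonlite::read_json(file.path(index_dir, "schema.json")))
  st <- new.env(parent = emptyenv())
  st$dir <- index_dir
  st$schema <- schema
  st$mapping <- jsonlite::read_json(file.path(index_dir, "mapping.json"))
  lines <- readLines(file.path(index_dir, "documents.ndjson"), warn = FALSE)
  st$docs <- lapply(lines, function(ln) {
    d <- jsonlite::fromJSON(ln, simplifyVector = FALSE)
    d$pos <- as.integer(d$pos)
    d$source_line <- as.integer(d$source_line)
    d
  })
  fl <- jsonlite::read_json(file.path(index_dir, "flags.json"))
  st$flags <- fl
  st$persist <- TRUE
  class(st) <- "vs_store"
  st
}

#' @export
print.vs_store <- function(x, ...) {
  cat("<vs_store> ", length(x$docs), " documents, ",
      length(x$schema$fields), " fields, dir=", x$dir, "\n", sep = "")
  invisible(x)
}

#' Documents currently in a store (flags applied)
#'
#' @param store a `vs_store`.
#' @return list of variant documents in insertion order.
#' @export
store_docs <- function(store) {
  if (!length(store$flags)) return(store$docs)
  lapply(store$docs, function(d) {
    fl <- store$flags[[variant_key_string(d)]]
    if (!is.null(fl)) d$flag <- fl
    d
  })
}

#' Canonical serialized dump of a store's documents
#'
#' Documents are ordered by source line and ALT allele and serialized; two
#' stores hold the same content iff their dumps are byte-identical. The
#' default binary form is fast for large stores; `format = "json"` gives a
#' human-readable per-document dump.
#'
#' @param store a `vs_store`.
#' @param format `"binary"` (a raw vector) or `"json"` (character vector,
#'   one JSON string per document).
#' @return raw vector or character vector, depending on `format`.
#' @export
canonical_dump <- function(store, format = c("binary", "json")) {
  format <- match.arg(format)
  docs <- store_docs(store)
  ord <- order(vapply(docs, `[[`, 1L, "source_line"),
               vapply(docs, `[[`, "", "alt"))
  if (format == "json") {
    return(vapply(docs[ord], doc_to_json, ""))
  }
  serialize(docs[ord], connection = NULL, version = 2)
}
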