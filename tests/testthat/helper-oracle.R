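# Independent oracles used by the property-style tests:
#  - naive_execute(): a plain nested-loop full-scan evaluator for scoped
#    include/exclude queries, written separately from the query engine.
#  - random_query(): draws validated queries of mixed scopes / operators /
#    polarities from a schema.
#  - oracle_inheritance(): direct boolean encoding of the seven trio rule
#    tables (strict-missing semantics).

oracle_scope <- function(schema, name) {
  switch(schema$fields[[name]]$source,
    core = "variant", info_flat = "variant",
    csq_nested = "transcript", sample_format = "sample")
}

oracle_value <- function(doc, scope, name, tr = NULL, se = NULL) {
  if (scope == "variant") {
    v <- switch(name,
      CHROM = doc$chrom, POS = doc$pos, REF = doc$ref, ALT = doc$alt,
      QUAL = doc$qual, FILTER = doc$filter_status, dbsnp_id = doc$dbsnp_id,
      flag = doc$flag, doc$flat_attributes[[name]])
    return(v)
  }
  if (scope == "transcript") return(tr[[name]])
  switch(name, Sample_ID = se$sample_id, GT = se$gt_raw,
         se$format_values[[name]])
}

oracle_test <- function(val, op, vals, numeric) {
  if (op == "exists") return(!is.null(val))
  if (op == "not_exists") return(is.null(val))
  if (is.null(val)) return(FALSE)
  if (numeric) {
    v <- suppressWarnings(as.numeric(val))
    if (is.na(v)) return(FALSE)
    vals <- as.numeric(vals)
    if (op == "eq" || op == "in") return(v %in% vals)
    if (op == "lt") return(v < vals[1])
    if (op == "le") return(v <= vals[1])
    if (op == "gt") return(v > vals[1])
    return(v >= vals[1])
  }
  as.character(val) %in% as.character(vals)
}

naive_execute <- function(store, query) {
  schema <- store$schema
  docs <- store_docs(store)
  fls <- lapply(query$filters, function(f) {
    list(field = f$field, op = f$operator, vals = f$values,
         pol = f$polarity, scope = oracle_scope(schema, f$field),
         num = schema$fields[[f$field]]$data_type %in% c("integer", "float"))
  })
  attrs <- lapply(query$attributes, function(a)
    list(name = a, scope = oracle_scope(schema, a)))
  out <- list()
  for (doc in docs) {
    # single-filter truth on the whole document
    holds1 <- function(f) {
      if (f$scope == "variant") {
        return(oracle_test(oracle_value(doc, "variant", f$field), f$op, f$vals, f$num))
      }
      entries <- if (f$scope == "transcript") doc$transcript_annotations else doc$sample_entries
      for (e in entries) {
        v <- if (f$scope == "transcript") oracle_value(doc, "transcript", f$field, tr = e)
             else oracle_value(doc, "sample", f$field, se = e)
        if (oracle_test(v, f$op, f$vals, f$num)) return(TRUE)
      }
      FALSE
    }
    inc <- Filter(function(f) f$pol == "include", fls)
    exc <- Filter(function(f) f$pol == "exclude", fls)
    ok <- TRUE
    for (f in Filter(function(f) f$scope == "variant", inc)) {
      if (!holds1(f)) { ok <- FALSE; break }
    }
    # same-entry conjunction for nested include scopes
    joint_idx <- function(entries, fs, scope) {
      keep <- c()
      for (i in seq_along(entries)) {
        all_ok <- TRUE
        for (f in fs) {
          v <- if (scope == "transcript") oracle_value(doc, scope, f$field, tr = entries[[i]])
               else oracle_value(doc, scope, f$field, se = entries[[i]])
          if (!oracle_test(v, f$op, f$vals, f$num)) { all_ok <- FALSE; break }
        }
        if (all_ok) keep <- c(keep, i)
      }
      keep
    }
    inc_t <- Filter(function(f) f$scope == "transcript", inc)
    inc_s <- Filter(function(f) f$scope == "sample", inc)
    t_keep <- joint_idx(doc$transcript_annotations, inc_t, "transcript")
    s_keep <- joint_idx(doc$sample_entries, inc_s, "sample")
    if (ok && length(inc_t) && !length(t_keep)) ok <- FALSE
    if (ok && length(inc_s) && !length(s_keep)) ok <- FALSE
    if (ok) for (f in exc) if (holds1(f)) { ok <- FALSE; break }
    if (!ok) next
    want_t <- any(vapply(attrs, function(a) a$scope == "transcript", TRUE))
    want_s <- any(vapply(attrs, function(a) a$scope == "sample", TRUE))
    ti <- if (want_t) { if (length(t_keep)) t_keep else NA_integer_ } else NA_integer_
    si <- if (want_s) { if (length(s_keep)) s_keep else NA_integer_ } else NA_integer_
    for (a_t in ti) for (a_s in si) {
      cells <- vapply(attrs, function(a) {
        v <- switch(a$scope,
          variant = oracle_value(doc, "variant", a$name),
          transcript = if (is.na(a_t)) NULL else
            oracle_value(doc, "transcript", a$name,
                         tr = doc$transcript_annotations[[a_t]]),
          sample = if (is.na(a_s)) NULL else
            oracle_value(doc, "sample", a$name, se = doc$sample_entries[[a_s]]))
        if (is.null(v)) NA_character_ else as.character(v)
      }, "")
      out[[length(out) + 1L]] <- cells
    }
  }
  out
}

canon_rows_df <- function(df) {
  if (!nrow(df)) return(character(0))
  sort(do.call(paste, c(lapply(df, as.character), sep = "\x01")))
}

canon_rows_list <- function(rows) {
  if (!length(rows)) return(character(0))
  sort(vapply(rows, paste, "", collapse = "\x01"))
}

random_query <- function(schema, rng_n = 3L) {
  pool <- list(
    list(field = "CHROM", op = "in",
         vals = sample(schema$fields$CHROM$values,
                       min(3, length(schema$fields$CHROM$values)))),
    list(field = "POS", op = sample(c("lt", "le", "gt", "ge"), 1),
         vals = sample(1e3:9e4, 1)),
    list(field = "QUAL", op = sample(c("lt", "ge"), 1),
         vals = round(runif(1, 100, 1500), 1)),
    list(field = "FILTER", op = "eq", vals = "PASS"),
    list(field = "AF", op = sample(c("lt", "ge"), 1),
         vals = round(runif(1, 0.05, 0.6), 3)),
    list(field = "AN", op = "ge", vals = sample(10:40, 1)),
    list(field = "DB", op = sample(c("exists", "not_exists"), 1), vals = NULL),
    list(field = "dbsnp_id", op = sample(c("exists", "not_exists"), 1),
         vals = NULL),
    list(field = "Consequence", op = "in",
         vals = sample(schema$fields$Consequence$values,
                       min(3, length(schema$fields$Consequence$values)))),
    list(field = "IMPACT", op = "in",
         vals = sample(c("HIGH", "MODERATE", "LOW", "MODIFIER"),
                       sample(1:2, 1))),
    list(field = "Sample_ID", op = "in",
         vals = sample(schema$samples, min(2, length(schema$samples)))),
    list(field = "GT", op = "in", vals = c("0|1", "1|0", "0/1", "1/0")),
    list(field = "DP", op = sample(c("ge", "lt"), 1), vals = sample(20:50, 1)),
    list(field = "GQ", op = "ge", vals = sample(30:90, 1))
  )
  n_f <- sample(seq_len(rng_n), 1)
  picks <- sample(length(pool), n_f)
  filters <- lapply(pool[picks], function(p) {
    filter_spec(p$field, p$op, p$vals,
                polarity = sample(c("include", "exclude"), 1,
                                  prob = c(0.8, 0.2)))
  })
  attr_pool <- c("CHROM", "POS", "REF", "ALT", "QUAL", "FILTER")
  attrs <- c("CHROM", "POS", "REF", "ALT")
  if (runif(1) < 0.4) attrs <- c(attrs, "IMPACT", "SYMBOL")
  if (runif(1) < 0.3) attrs <- c(attrs, "Sample_ID", "GT")
  vs_query(attributes = attrs, filters = filters)
}

oracle_inheritance <- function(model, ch, fa, mo, on_x, sex,
                               aff = c(child = "affected",
                                       father = "unaffected",
                                       mother = "unaffected")) {
  if (ch == "MISSING" || fa == "MISSING" || mo == "MISSING") return(FALSE)
  if (aff[["child"]] == "unaffected") return(FALSE)
  carries_x <- function(g, s) {
    if (s == "male") g == "HOM_ALT" else if (s == "female") g == "HET" else NA
  }
  pst <- aff[c("father", "mother")]
  switch(model,
    autosomal_de_novo =
      !on_x && ch == "HET" && fa == "HOM_REF" && mo == "HOM_REF",
    autosomal_dominant = {
      if (on_x || ch != "HET" || any(pst == "unknown")) FALSE
      else {
        f_ok <- if (pst[["father"]] == "affected") fa == "HET" else fa == "HOM_REF"
        m_ok <- if (pst[["mother"]] == "affected") mo == "HET" else mo == "HOM_REF"
        f_ok && m_ok && any(pst == "affected")
      }
    },
    autosomal_recessive =
      !on_x && ch == "HOM_ALT" && fa == "HET" && mo == "HET",
    compound_heterozygous =
      !on_x && ch == "HET" &&
        ((fa %in% c("HET", "HOM_ALT") && mo == "HOM_REF") ||
         (mo %in% c("HET", "HOM_ALT") && fa == "HOM_REF")),
    x_linked_de_novo = {
      cx <- carries_x(ch, sex)
      on_x && isTRUE(cx) && fa == "HOM_REF" && mo == "HOM_REF"
    },
    x_linked_dominant = {
      cx <- carries_x(ch, sex)
      if (!on_x || !isTRUE(cx) || any(pst == "unknown")) FALSE
      else {
        f_ok <- if (pst[["father"]] == "affected") fa == "HOM_ALT" else fa == "HOM_REF"
        m_ok <- if (pst[["mother"]] == "affected") mo == "HET" else mo == "HOM_REF"
        f_ok && m_ok && any(pst == "affected")
      }
    },
    x_linked_recessive = {
      if (!on_x) FALSE
      else if (sex == "male") ch == "HOM_ALT" && mo == "HET" && fa == "HOM_REF"
      else if (sex == "female") ch == "HOM_ALT" && mo == "HET" && fa == "HOM_ALT"
      else FALSE
    })
}
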