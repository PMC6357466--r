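hla_style_lines <- function() {
  # a handful of hand-written lines mirroring published query idioms:
  # range filters on POS, categorical Consequence, per-sample het GT filters
  c(paste0("6\t28477797\trs100\tA\tG\t80\tPASS\tAC=1;AN=6;AF=0.167;",
           "CSQ=G|missense_variant|MODERATE|HLA1\tGT:DP:GQ\t0|1:30:90\t0/0:25:80\t0/0:22:70"),
    paste0("6\t30000000\t.\tC\tT\t90\tPASS\tAC=2;AN=6;AF=0.333;DB;",
           "CSQ=T|stop_gained|HIGH|HLA2\tGT:DP:GQ\t0/0:30:90\t1|0:25:80\t0|1:22:70"),
    paste0("6\t33448354\trs101\tG\tA\t70\tq10\tAC=1;AN=6;AF=0.167;",
           "CSQ=A|intron_variant|MODIFIER|HLA2\tGT:DP:GQ\t0/0:30:90\t0/0:25:80\t1/1:22:70"),
    paste0("7\t1000\t.\tT\tC\t60\tPASS\tAC=1;AN=6;AF=0.167;",
           "CSQ=C|missense_variant|MODERATE|OTHER1\tGT:DP:GQ\t0|1:30:90\t0/0:25:80\t0/0:22:70"))
}

test_that("validation enforces field existence, scope and operator typing", {
  store <- mini_store(hla_style_lines())
  schema <- store$schema
  # novel-and-detrimental idiom: dbsnp excluded, IMPACT HIGH, FILTER PASS
  q1 <- vs_query(attributes = c("CHROM", "POS", "REF", "ALT", "IMPACT"),
                 filters = list(filter_spec("dbsnp_id", "not_exists"),
                                filter_spec("IMPACT", "in", "HIGH"),
                                filter_spec("FILTER", "eq", "PASS")))
  expect_s3_class(validate_query(q1, schema), "vs_compiled_query")
  # positional window idiom
  q2 <- vs_query(attributes = c("CHROM", "POS"),
                 filters = list(filter_spec("CHROM", "eq", "6"),
                                filter_spec("POS", "ge", 28477797),
                                filter_spec("POS", "le", 33448354),
                                filter_spec("Consequence", "in", "missense_variant")))
  expect_s3_class(validate_query(q2, schema), "vs_compiled_query")
  # type and shape errors
  expect_error(validate_query(
    vs_query("CHROM", list(filter_spec("IMPACT", "lt", 1))), schema),
    "numeric")
  expect_error(validate_query(
    vs_query("CHROM", list(filter_spec("NOPE", "eq", 1))), schema),
    "unknown filter field")
  expect_error(validate_query(
    vs_query(character(0), list()), schema), "empty")
  expect_error(validate_query(
    vs_query("CHROM", list(filter_spec("POS", "in", NULL))), schema),
    "at least one value")
})

test_that("execution applies scoped conjunctive semantics", {
  store <- mini_store(hla_style_lines())
  schema <- store$schema
  # no filters: every document, untruncated
  all_q <- validate_query(vs_query(c("CHROM", "POS")), schema)
  res <- execute(all_q, store)
  expect_equal(res$total_matched, 4)
  expect_false(res$truncated)

  # het-in-selected-samples idiom, same-entry semantics
  het_q <- validate_query(
    vs_query(c("CHROM", "POS", "Sample_ID", "GT"),
             filters = list(filter_spec("Sample_ID", "in", c("HG003", "HG004")),
                            filter_spec("GT", "in", c("0|1", "1|0")))), schema)
  r <- execute(het_q, store, mode = "full")
  # line1: HG002 het only -> no; line2: HG003 het 1|0 and HG004 het 0|1 -> yes
  # line3: HG004 hom-alt -> no; line4: HG002 het only -> no
  expect_equal(unique(r$rows$POS), 30000000)
  expect_setequal(r$rows$Sample_ID, c("HG003", "HG004"))

  # same-entry negative: sample A het at v1, B het at v2 must not match at v2
  two <- mini_store(c(
    "1\t10\t.\tA\tG\t50\tPASS\tAC=1;AN=4;AF=0.25\tGT:DP:GQ\t0/1:30:80\t0/0:20:70\t0/0:20:70",
    "1\t20\t.\tC\tT\t50\tPASS\tAC=1;AN=4;AF=0.25\tGT:DP:GQ\t0/0:30:80\t0/1:20:70\t0/0:20:70"))
  cj <- validate_query(
    vs_query(c("CHROM", "POS"),
             filters = list(filter_spec("Sample_ID", "eq", "HG002"),
                            filter_spec("GT", "in", c("0/1", "0|1")))),
    two$schema)
  rr <- execute(cj, two, mode = "full")
  expect_equal(rr$rows$POS, 10)

  # transcript-scoped joint match
  tq <- validate_query(
    vs_query(c("CHROM", "POS", "SYMBOL"),
             filters = list(filter_spec("IMPACT", "eq", "HIGH"),
                            filter_spec("SYMBOL", "eq", "HLA2"))), schema)
  rt <- execute(tq, store, mode = "full")
  expect_equal(rt$rows$POS, 30000000)

  # unvalidated queries are rejected
  expect_error(execute(vs_query("CHROM"), store), "validate")
})

test_that("display cap truncates while export returns everything", {
  fx <- simulate_multisample_vcf(500, 3, "generic", seed = 71)
  store <- create_index(infer_schema(fx$vcf_path), persist = FALSE)
  ingest_vcf(fx$vcf_path, store)
  q <- validate_query(vs_query(c("CHROM", "POS", "REF", "ALT")), store$schema)
  disp <- execute(q, store, mode = "display")
  expect_equal(nrow(disp$rows), 400)
  expect_true(disp$truncated)
  expect_equal(disp$total_matched, 500)
  full <- execute(q, store, mode = "full")
  expect_equal(nrow(full$rows), 500)
  # display rows are a prefix of full rows in store order
  expect_identical(disp$rows, full$rows[1:400, ])
  # custom cap
  d10 <- execute(q, store, mode = "display", display_cap = 10)
  expect_equal(nrow(d10$rows), 10)

  path <- tempfile(fileext = ".csv")
  n <- export_csv(q, store, path)
  expect_equal(n, 500)
  got <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(got), 500)
  expect_identical(names(got), c("CHROM", "POS", "REF", "ALT"))

  # attribute reordering permutes columns
  q2 <- validate_query(vs_query(c("ALT", "CHROM", "POS", "REF")), store$schema)
  export_csv(q2, store, path)
  got2 <- utils::read.csv(path, check.names = FALSE)
  expect_identical(names(got2), c("ALT", "CHROM", "POS", "REF"))
  expect_identical(as.character(got2$ALT), as.character(got$ALT))

  # empty result: header-only CSV
  q0 <- validate_query(
    vs_query("CHROM", filters = list(filter_spec("CHROM", "eq", "ZZ"))),
    store$schema)
  expect_equal(export_csv(q0, store, path), 0)
  expect_equal(length(readLines(path)), 1)
})

test_that("exclude polarity is the exact complement for variant filters", {
  fx <- simulate_multisample_vcf(200, 4, "vep", seed = 72)
  store <- create_index(infer_schema(fx$vcf_path), persist = FALSE)
  ingest_vcf(fx$vcf_path, store)
  attrs <- c("CHROM", "POS", "REF", "ALT")
  specs <- list(
    list("FILTER", "eq", "PASS"),
    list("QUAL", "lt", 800),
    list("dbsnp_id", "exists", NULL),
    list("AF", "ge", 0.2))
  all_rows <- canon_rows_df(
    execute(validate_query(vs_query(attrs), store$schema), store, "full")$rows)
  for (s in specs) {
    qi <- validate_query(vs_query(attrs, list(
      filter_spec(s[[1]], s[[2]], s[[3]], "include"))), store$schema)
    qe <- validate_query(vs_query(attrs, list(
      filter_spec(s[[1]], s[[2]], s[[3]], "exclude"))), store$schema)
    ri <- canon_rows_df(execute(qi, store, "full")$rows)
    re <- canon_rows_df(execute(qe, store, "full")$rows)
    expect_length(intersect(ri, re), 0)
    expect_setequal(c(ri, re), all_rows)
  }
})

test_that("random scoped queries agree with the naive full-scan oracle", {
  fx <- simulate_multisample_vcf(300, 6, "vep", seed = 73,
                                 multiallelic_fraction = 0.05)
  store <- create_index(infer_schema(fx$vcf_path), persist = FALSE)
  ingest_vcf(fx$vcf_path, store)
  set.seed(74)
  for (i in 1:40) {
    q <- random_query(store$schema)
    cq <- validate_query(q, store$schema)
    mine <- canon_rows_df(execute(cq, store, mode = "full")$rows)
    theirs <- canon_rows_list(naive_execute(store, q))
    expect_identical(mine, theirs)
  }
})

test_that("saved queries round-trip and re-execute identically", {
  store <- mini_store(hla_style_lines())
  reg <- tempfile(fileext = ".json")
  q <- vs_query(c("CHROM", "POS", "REF", "ALT"),
                filters = list(filter_spec("FILTER", "eq", "PASS"),
                               filter_spec("POS", "ge", 2000)))
  save_query("hla", q, reg)
  back <- recall_query("hla", reg)
  expect_identical(query_to_list_for_test(back), query_to_list_for_test(q))
  r1 <- execute(validate_query(q, store$schema), store, mode = "full")
  r2 <- execute(validate_query(back, store$schema), store, mode = "full")
  expect_identical(r1$rows, r2$rows)
  expect_error(recall_query("nope", reg), "no saved query")
  expect_error(save_query("hla", q, reg), "already exists")
  expect_no_error(save_query("hla", q, reg, overwrite = TRUE))
})

test_that("rejected flags remove variants via an exclude filter", {
  store <- mini_store(hla_style_lines())
  d <- store$docs[[2]]
  set_flag(store, d$chrom, d$pos, d$ref, d$alt, "Rejected")
  q <- validate_query(
    vs_query(c("CHROM", "POS"),
             filters = list(filter_spec("flag", "eq", "Rejected",
                                        polarity = "exclude"))),
    store$schema)
  res <- execute(q, store, mode = "full")
  expect_false(d$pos %in% res$rows$POS)
  expect_equal(nrow(res$rows), 3)
  # clearing restores it
  set_flag(store, d$chrom, d$pos, d$ref, d$alt, "clear")
  expect_equal(nrow(execute(q, store, mode = "full")$rows), 4)
  expect_error(set_flag(store, "9", 1, "A", "T", "Approved"), "no variant")
})

test_that("external links are deterministic templates over the variant key", {
  store <- mini_store(hla_style_lines())
  doc <- store$docs[[2]]   # chrom 6, pos 30000000, SYMBOL HLA2
  links <- build_external_links(doc)
  expect_match(links$ucsc, "chr6")
  expect_match(links$ucsc, "29999500-30000500")
  expect_match(links$decipher, "6:30000000")
  expect_match(links$genemania, "HLA2")
  expect_identical(links, build_external_links(doc))
  # no gene symbol -> no GeneMANIA entry
  doc2 <- doc
  doc2$transcript_annotations <- list()
  expect_null(build_external_links(doc2)$genemania)
})
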