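test_that("INFO strings parse into typed attribute-value pairs", {
  expect_identical(parse_info_pairs("."), stats::setNames(list(), character(0)))
  p <- parse_info_pairs("AC=2;AN=6;DB")
  expect_equal(p$AC, 2)
  expect_equal(p$AN, 6)
  expect_true(p$DB)
  # CSQ is routed elsewhere, never included here
  p2 <- parse_info_pairs("AF=0.5;CSQ=A|missense_variant|MODERATE|GENE1")
  expect_named(p2, "AF")
  expect_equal(p2$AF, 0.5)
  expect_error(parse_info_pairs("=5"), "malformed INFO pair")
})

test_that("INFO parsing agrees with an independent VCF parser on a fixture", {
  fx <- simulate_multisample_vcf(60, 4, "annovar", seed = 402)
  v <- vcfR::read.vcfR(fx$vcf_path, verbose = FALSE)
  raw_info <- v@fix[, "INFO"]
  schema <- infer_schema(fx$vcf_path)
  for (i in seq_along(raw_info)) {
    mine <- parse_info_pairs(raw_info[i], schema)
    an <- as.numeric(vcfR::extract.info(v, "AN")[i])
    af <- as.numeric(vcfR::extract.info(v, "gnomAD_AF")[i])
    gene <- vcfR::extract.info(v, "Gene.refGene")[i]
    expect_equal(mine$AN, an)
    expect_equal(mine$gnomAD_AF, af)
    expect_identical(mine$Gene.refGene, gene)
  }
})

test_that("CSQ blocks split into per-transcript annotations positionally", {
  fmt <- c("Allele", "Consequence", "IMPACT", "SYMBOL")
  one <- parse_csq_block("A|missense_variant|MODERATE|GENE1", fmt)
  expect_length(one, 1)
  expect_identical(one[[1]]$SYMBOL, "GENE1")
  two <- parse_csq_block(
    "A|missense_variant|MODERATE|GENE1,A|intron_variant|MODIFIER|GENE1", fmt)
  expect_length(two, 2)
  expect_identical(two[[2]]$Consequence, "intron_variant")
  # empty positions omitted
  sparse <- parse_csq_block("A||MODIFIER|", fmt)
  expect_named(sparse[[1]], c("Allele", "IMPACT"))
  expect_error(parse_csq_block("A|x|y|z|EXTRA", fmt), "entry 1")
  # split-count oracle: entries = comma count + 1 on random payloads
  set.seed(7)
  for (rep in 1:20) {
    n <- sample(1:6, 1)
    payload <- paste(replicate(n, paste(sample(letters, 4), collapse = "|")),
                     collapse = ",")
    expect_length(parse_csq_block(payload, fmt), n)
  }
})

test_that("genotype classification matches an exhaustive enumeration", {
  expect_identical(classify_genotype("0/0"), "HOM_REF")
  expect_identical(classify_genotype("0|1"), "HET")
  expect_identical(classify_genotype("1|0"), "HET")
  expect_error(classify_genotype(""), "non-empty")
  # enumeration oracle over alleles {0,1,2,.} x separators {/,|}
  alleles <- c("0", "1", "2", ".")
  for (a1 in alleles) for (a2 in alleles) for (sep in c("/", "|")) {
    gt <- paste0(a1, sep, a2)
    expected <- if (a1 == "." || a2 == ".") "MISSING"
      else if (a1 == "0" && a2 == "0") "HOM_REF"
      else if (xor(a1 == "0", a2 == "0")) "HET"
      else if (a1 == a2) "HOM_ALT"
      else "OTHER"
    expect_identical(classify_genotype(gt), expected)
  }
  # haploid calls are OTHER (hemizygous handling is a Mendelian-module concern)
  expect_identical(classify_genotype("1"), "OTHER")
  expect_identical(classify_genotype("1/2"), "OTHER")
})

test_that("sample entries are sparse: hom-ref absent, missing stored", {
  fmt <- c("GT", "DP")
  ids <- c("A", "B", "C")
  expect_length(parse_sample_entries(fmt, c("0/0:30", "0|0:12", "0/0:9"), ids), 0)
  e <- parse_sample_entries(fmt, c("0/0:30", "0|1:25", "./.:0"), ids)
  expect_length(e, 2)
  expect_identical(vapply(e, `[[`, "", "sample_id"), c("B", "C"))
  expect_identical(e[[1]]$gt_raw, "0|1")
  expect_identical(e[[1]]$gt_class, "HET")
  expect_equal(e[[1]]$format_values$DP, 25)
  expect_identical(e[[2]]$gt_class, "MISSING")
  expect_error(parse_sample_entries(fmt, c("0/1", "0/1:2", "0/1:3"), ids),
               "sample A")
})

test_that("records decompose into one document per ALT allele", {
  schema <- infer_schema(write_mini_vcf(
    "1\t100\trs1\tA\tG\t50\tPASS\tAC=1;AN=6;AF=0.167\tGT:DP:GQ\t0/1:30:80\t0/0:22:70\t0/0:25:60"))
  line1 <- "1\t100\trs1\tA\tG\t50\tPASS\tAC=1;AN=6;AF=0.167\tGT:DP:GQ\t0/1:30:80\t0/0:22:70\t0/0:25:60"
  d <- decompose_record(line1, schema)
  expect_length(d, 1)
  expect_identical(d[[1]]$dbsnp_id, "rs1")
  expect_equal(d[[1]]$pos, 100L)

  # triallelic: 2 docs sharing chrom/pos/ref, Number=A INFO split positionally
  line2 <- "1\t200\t.\tA\tC,T\t60\tPASS\tAC=2,1;AN=6;AF=0.333,0.167\tGT:DP:GQ\t0/1:30:80\t1/2:22:70\t0/0:25:60"
  d2 <- decompose_record(line2, schema)
  expect_length(d2, 2)
  expect_identical(vapply(d2, `[[`, "", "alt"), c("C", "T"))
  expect_equal(d2[[1]]$flat_attributes$AC, 2L)
  expect_equal(d2[[2]]$flat_attributes$AC, 1L)
  expect_equal(d2[[2]]$flat_attributes$AF, 0.167)
  expect_null(d2[[1]]$dbsnp_id)
  # sample 2 is 1/2: HET for each allele's document? no - one target copy plus
  # another alt allele, so OTHER, with one alt copy recorded
  s2 <- d2[[1]]$sample_entries
  cls <- vapply(s2, `[[`, "", "gt_class")
  expect_true("OTHER" %in% cls)

  # monomorphic ALT is skipped
  d3 <- decompose_record("1\t300\t.\tA\t.\t10\tPASS\tAN=6\tGT:DP:GQ\t0/0:1:2\t0/0:1:2\t0/0:1:2",
                         schema)
  expect_length(d3, 0)
  expect_true(attr(d3, "monomorphic"))
})

test_that("CSQ annotations attach to the document whose ALT matches Allele", {
  line <- paste0("1\t400\t.\tA\tC,T\t60\tPASS\t",
                 "AC=1,1;AN=6;AF=0.1,0.1;CSQ=C|missense_variant|HIGH|G1,",
                 "T|intron_variant|MODIFIER|G1,C|stop_gained|HIGH|G2",
                 "\tGT:DP:GQ\t0/1:30:80\t0/2:22:70\t0/0:25:60")
  schema <- infer_schema(write_mini_vcf(line))
  d <- decompose_record(line, schema)
  expect_length(d[[1]]$transcript_annotations, 2)
  expect_length(d[[2]]$transcript_annotations, 1)
  expect_identical(d[[2]]$transcript_annotations[[1]]$Consequence,
                   "intron_variant")
})

test_that("schema inference assigns types, widgets and display groups", {
  fx <- simulate_multisample_vcf(80, 6, "vep", seed = 21)
  schema <- infer_schema(fx$vcf_path)
  f <- schema$fields
  expect_identical(f$AF$data_type, "float")
  expect_identical(f$AF$widget, "range")
  expect_identical(f$POS$widget, "range")
  expect_identical(f$IMPACT$data_type, "categorical")
  expect_identical(f$IMPACT$widget, "dropdown")
  expect_true(all(f$IMPACT$values %in% c("HIGH", "MODERATE", "LOW", "MODIFIER")))
  expect_identical(f$DB$data_type, "flag")
  expect_identical(f$DB$widget, "checkbox")
  expect_identical(f$dbsnp_id$widget, "excluded_toggle")
  expect_identical(f$CHROM$group, "Variant Related Information")
  expect_identical(f$Consequence$group, "Variant Related Information")
  expect_identical(f$GT$group, "Sample Related Information")
  expect_identical(f$DP$group, "Sample Related Information")
  expect_identical(f$Sample_ID$source, "sample_format")
  # header missing the #CHROM line is fatal
  bad <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2", "1\t1\t.\tA\tT\t1\tPASS\t."), bad)
  expect_error(infer_schema(bad), "#CHROM")
})

test_that("chunk plans are balanced, disjoint and covering", {
  fx <- simulate_multisample_vcf(10, 2, "generic", seed = 5)
  p1 <- plan_chunks(fx$vcf_path, 1)
  expect_length(p1, 1)
  expect_equal(p1[[1]]$n_lines, 10L)
  p4 <- plan_chunks(fx$vcf_path, 4)
  sizes <- vapply(p4, `[[`, 0L, "n_lines")
  expect_equal(sort(sizes, decreasing = TRUE), c(3L, 3L, 2L, 2L))
  starts <- vapply(p4, `[[`, 0L, "first_data_line")
  expect_equal(starts, c(0L, cumsum(sizes)[-4]))
  # more workers than lines: one chunk per line
  p99 <- plan_chunks(fx$vcf_path, 99)
  expect_length(p99, 10)
  # balanced-partition oracle across random cases
  fx2 <- simulate_multisample_vcf(37, 2, "generic", seed = 6)
  for (w in c(2, 3, 5, 8)) {
    p <- plan_chunks(fx2$vcf_path, w)
    sz <- vapply(p, `[[`, 0L, "n_lines")
    expect_equal(sum(sz), 37L)
    expect_lte(diff(range(sz)), 1L)
  }
})

test_that("parallel and serial ingest store identical documents", {
  fx <- simulate_multisample_vcf(200, 8, "vep", seed = 31,
                                 multiallelic_fraction = 0.1)
  dumps <- lapply(c(1, 2, 4), function(w) {
    st <- create_index(infer_schema(fx$vcf_path), persist = FALSE)
    ingest_vcf(fx$vcf_path, st, n_workers = w)
    canonical_dump(st)
  })
  expect_identical(dumps[[1]], dumps[[2]])
  expect_identical(dumps[[1]], dumps[[3]])
})

test_that("ingest counts documents per ALT allele and round-trips core fields", {
  fx <- simulate_multisample_vcf(100, 5, "vep", seed = 41,
                                 multiallelic_fraction = 0.15)
  st <- create_index(infer_schema(fx$vcf_path), persist = FALSE)
  rep <- ingest_vcf(fx$vcf_path, st)
  expect_equal(rep$n_data_lines, 100L)
  expect_equal(rep$n_documents, fx$truth$n_documents)
  expect_gte(rep$n_documents, rep$n_data_lines)
  expect_equal(rep$n_documents, sum(rep$per_chunk_document_counts))
  # round-trip against raw lines
  raw <- readLines(fx$vcf_path)
  raw <- raw[!startsWith(raw, "#")]
  docs <- store_docs(st)
  by_line <- split(docs, vapply(docs, `[[`, 1L, "source_line"))
  for (i in seq_along(raw)) {
    f <- strsplit(raw[i], "\t", fixed = TRUE)[[1]]
    for (d in by_line[[as.character(i)]]) {
      expect_identical(d$chrom, f[1])
      expect_equal(d$pos, as.integer(f[2]))
      expect_identical(d$ref, f[4])
      expect_true(d$alt %in% strsplit(f[5], ",", fixed = TRUE)[[1]])
      expect_equal(d$qual, as.numeric(f[6]))
      expect_identical(d$filter_status, f[7])
    }
  }
})

test_that("sparsity accounting matches the raw genotype matrix", {
  fx <- simulate_multisample_vcf(150, 6, "vep", seed = 51, alt_fraction = 0.4)
  st <- create_index(infer_schema(fx$vcf_path), persist = FALSE)
  ingest_vcf(fx$vcf_path, st)
  stored <- sum(vapply(store_docs(st), function(d) length(d$sample_entries), 0L))
  # direct count from the raw VCF
  raw <- readLines(fx$vcf_path)
  raw <- raw[!startsWith(raw, "#")]
  direct <- 0L
  for (ln in raw) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    gts <- vapply(strsplit(f[10:length(f)], ":", fixed = TRUE), `[[`, "", 1)
    direct <- direct + sum(!gts %in% c("0/0", "0|0"))
  }
  expect_equal(stored, direct)
  expect_equal(stored, fx$truth$total_sample_entries)
})
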