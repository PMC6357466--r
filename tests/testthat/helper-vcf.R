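# Tiny literal-VCF builder for unit tests. The fixture generators in the
# package cover realistic inputs; this helper exists for hand-crafted edge
# cases (multi-allelic lines, missing genotypes, specific CSQ payloads).

mini_vcf_header <- function(samples, contigs = c("1", "2", "6", "X"),
                            with_csq = TRUE) {
  h <- c("##fileformat=VCFv4.2",
         paste0("##contig=<ID=", contigs, ">"),
         "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Alt allele count\">",
         "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
         "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Alt allele frequency\">",
         "##INFO=<ID=DB,Number=0,Type=Flag,Description=\"dbSNP membership\">",
         "##INFO=<ID=EUR_AF,Number=A,Type=Float,Description=\"European AF\">")
  if (with_csq) {
    h <- c(h, paste0("##INFO=<ID=CSQ,Number=.,Type=String,Description=",
                     "\"Consequence annotations from Ensembl VEP. Format: ",
                     "Allele|Consequence|IMPACT|SYMBOL\">"))
  }
  c(h,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
}

write_mini_vcf <- function(data_lines, samples = c("HG002", "HG003", "HG004"),
                           with_csq = TRUE,
                           path = tempfile(fileext = ".vcf")) {
  writeLines(c(mini_vcf_header(samples, with_csq = with_csq), data_lines), path)
  path
}

mini_store <- function(data_lines, samples = c("HG002", "HG003", "HG004"),
                       with_csq = TRUE, persist = FALSE) {
  path <- write_mini_vcf(data_lines, samples, with_csq)
  schema <- infer_schema(path)
  store <- create_index(schema, persist = persist)
  ingest_vcf(path, store)
  store
}

query_to_list_for_test <- function(q) {
  list(dataset = q$dataset, analysis_type = q$analysis_type,
       attributes = as.character(q$attributes),
       filters = lapply(q$filters, function(f)
         list(f$field, f$operator, as.character(f$values), f$polarity)))
}
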