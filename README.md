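# varscout

Exploration, Mendelian filtering and case/control comparison of annotated
multi-sample VCF cohorts, as an R package with a small command-line
interface.

Sequencing studies annotate their VCFs with VEP (nested `CSQ` per-transcript
consequence records) or Annovar (flat `key=value` INFO pairs) and then need
to *query* them: range filters on numeric annotations, term filters on
categorical ones, per-sample genotype constraints, trio inheritance logic,
and allele-frequency comparison against a control cohort. varscout parses
annotated VCFs — serially or in balanced parallel chunks — into a sparse
nested document store and answers those queries reproducibly.

## Data model and semantics in brief

* **One document per site × alternate allele.** Multi-allelic records are
  decomposed; `Number=A` INFO values are split positionally; CSQ entries are
  routed to the allele their `Allele` field names.
* **Sparse genotypes.** A per-sample entry is stored only when the call is
  not hom-ref, so absence ⇔ hom-ref; missing calls (`./.`) are stored so
  that an untyped parent is never mistaken for a hom-ref parent. Genotype
  classes: `HOM_REF`, `HET`, `HOM_ALT`, `MISSING`, `OTHER`.
* **Scoped conjunctive filters.** Include/exclude predicates at variant,
  transcript, or sample scope; nested include filters must be satisfied
  jointly by a *single* nested entry (so `Sample_ID ∈ {HG003, HG004}` and
  `GT ∈ {0|1, 1|0}` means "one of those samples is het", not "some sample
  is HG003 and some sample is het"). Display mode returns the first 400
  rows in store order; CSV export always returns everything.
* **Seven trio models.** Autosomal de novo / dominant / recessive, compound
  heterozygous, X-linked de novo / dominant / recessive, driven by a
  PLINK-style PED file, with the rule tables kept as data
  (`inheritance_rules()`) so a revised rule set is a data change. Strict
  missing-genotype handling by default, permissive wildcards on request,
  optional DP/GQ gates, hemizygous male X normalization.
* **Case/control.** Cohorts joined on (chrom, pos, ref, alt); per-site alt
  allele counts, called totals, frequencies, `present_in` provenance, and an
  optional Fisher exact p-value.

## Worked example

```r
library(varscout)

# a deterministic synthetic VEP-annotated cohort: 1000 sites, 8 samples
fx <- simulate_multisample_vcf(1000, 8, "vep", seed = 42)
schema <- infer_schema(fx$vcf_path)
store  <- create_index(schema, index_dir = tempfile())
rep <- ingest_vcf(fx$vcf_path, store, n_workers = 2)
rep$n_documents
#> [1] 1000
rep$per_chunk_document_counts
#> [1] 500 500

# novel, detrimental, PASS-filtered variants
q <- vs_query(
  attributes = c("CHROM", "POS", "REF", "ALT", "IMPACT", "SYMBOL"),
  filters = list(
    filter_spec("dbsnp_id", "not_exists"),
    filter_spec("IMPACT", "in", "HIGH"),
    filter_spec("FILTER", "eq", "PASS")))
res <- execute(validate_query(q, schema), store)
res$total_matched
#> [1] 292
head(res$rows, 3)
#>   CHROM   POS REF ALT IMPACT   SYMBOL
#> 1     1 28802   T   C   HIGH GENE0183
#> 2     1 30903   G   C   HIGH GENE0156
#> 3     1 30903   G   C   HIGH GENE0156
```

`res$total_matched` is the number of result rows before display capping
(one row per variant × matching transcript here, since a transcript-scoped
attribute was selected); `res$rows` holds at most 400 of them, and
`export_csv()` writes all of them.

A trio analysis:

```r
tx  <- simulate_trio(2000, planted = list(autosomal_de_novo = 5), seed = 7)
st  <- create_index(infer_schema(tx$vcf_path), persist = FALSE)
ingest_vcf(tx$vcf_path, st)
ped <- load_pedigree(tx$ped_path)
run_mendelian(st, ped, "autosomal_de_novo")
#>               model chrom    pos ref alt child_gt father_gt mother_gt    gene
#> 1 autosomal_de_novo     3 149916   G   C      HET   HOM_REF   HOM_REF PL00231
#> 2 autosomal_de_novo     4 168376   T   C      HET   HOM_REF   HOM_REF PL00299
#> 3 autosomal_de_novo     6 149179   G   C      HET   HOM_REF   HOM_REF PL00494
#> 4 autosomal_de_novo    18  25219   A   G      HET   HOM_REF   HOM_REF PL01551
#> 5 autosomal_de_novo    19  38617   T   C      HET   HOM_REF   HOM_REF PL01655
```

Those five hits are exactly the five planted de novo variants recorded in
the fixture's truth file.

The same operations are available from a shell via the wrapper installed at
`system.file("cli", "varscout", package = "varscout")` — subcommands `load`,
`query`, `export`, `flag`, `savequery`, `mendelian`, `casecontrol`,
`simulate`.

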