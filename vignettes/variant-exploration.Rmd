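---
title: "Exploring annotated variant cohorts with varscout"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exploring annotated variant cohorts with varscout}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varscout)
```

## The problem

Clinical and cohort sequencing studies produce multi-sample VCF files whose
INFO column has been enriched by an annotation tool — VEP, whose `CSQ` key
packs a comma-separated list of per-transcript consequence records, or
Annovar, which adds flat `key=value` pairs. Finding a candidate
disease-causing variant in such a file means combining range filters on
numeric annotations (allele frequency, position, quality), term filters on
categorical ones (consequence, impact, chromosome), per-sample genotype
constraints, pedigree logic, and sometimes a comparison against a control
cohort. varscout implements that workflow as a library plus a small CLI:
annotated VCFs are parsed into a document store, and everything downstream is
a query over those documents.

## The data model

Each stored document represents **one alternate allele at one site**.
Multi-allelic records are decomposed because the interesting predicates are
allele-specific: a frequency filter on a `Number=A` INFO field, or a
recessive-genotype test, refers to one ALT, not to the site. A document
carries three layers:

* **flat attributes** — the core columns (`CHROM`, `POS`, `REF`, `ALT`,
  `QUAL`, `FILTER`, the dbSNP identifier) and every flat INFO key, with
  `Number=A` values split positionally per allele;
* **nested transcript annotations** — one record per CSQ entry, keyed by the
  format declared in the VCF header; entries are routed to the document
  whose ALT matches their `Allele` field (or to all of the line's documents
  when no `Allele` field is present or it matches no ALT, so that
  annotations are never silently dropped);
* **sparse sample genotype entries** — one record per sample whose genotype
  is *not* hom-ref. Genotype data in cohort VCFs is overwhelmingly hom-ref,
  so absence encodes hom-ref. Missing calls (`./.`) **are** stored: the
  Mendelian rules must distinguish an untyped parent from a hom-ref parent,
  so absence must mean hom-ref unambiguously.

Genotypes are classified from the raw GT string (`HOM_REF`, `HET`,
`HOM_ALT`, `MISSING`, everything else `OTHER`); the phasing separator never
affects the class. Haploid calls are `OTHER` at the store level; the
Mendelian module normalizes haploid male X calls (`1` → hemizygous alt,
treated as `HOM_ALT`; `0` → `HOM_REF`).

## Schema inference and the UI configuration

`infer_schema()` reads the header and a sample of records (default 5,000)
and assigns each field a data type and a filter widget: numeric fields get
range filters, categorical fields (at most 50 distinct observed values by
default; configurable) get dropdowns with the sorted observed values, flags
get checkboxes, free text gets a search box, and optional identifiers such
as the dbSNP id get a present/absent toggle. Header `Type=` declarations win
over observed values, with a warning, because the header is the file's
contract. Fields are grouped into "Variant Related Information" (core, INFO
and CSQ fields) and "Sample Related Information" (FORMAT fields), and
`generate_ui_config()` emits a deterministic structured-text artifact that a
front end could render directly; the index mapping written next to it marks
each field range- or term-queryable and places CSQ and FORMAT fields in
nested blocks.

## Query semantics

Filters are conjunctive; disjunction is expressed through multi-value `in`
filters. Each filter is scoped by its field's origin: variant, transcript,
or sample. A variant matches when all include filters hold and no exclude
filter holds. Nested include filters use **same-entry semantics**: one
single transcript (or one single sample entry) must satisfy all
transcript-scoped (sample-scoped) include filters jointly — "sample HG003 is
het" must not match a document where HG003 carries nothing and some other
sample is het. Exclude filters are evaluated individually: a document is
dropped when any nested entry satisfies an exclude filter. For
variant-scoped filters this makes exclude the exact set complement of
include, which the tests assert.

Projection follows the scopes: selecting a nested attribute yields one row
per variant × matching nested entry (only entries matching the nested
include filters are projected); selecting attributes from both nested blocks
yields their cross product; a document with no matching nested entries for a
selected nested attribute keeps a single row with `NA` in those columns
rather than disappearing. Display mode truncates at 400 rows (configurable)
in store order — insertion order by source line, since no ranking is defined
for this kind of data — while CSV export always writes the full result.

## Mendelian analyses

Seven models are supported: autosomal de novo / dominant / recessive,
compound heterozygous, and X-linked de novo / dominant / recessive. The rule
tables live in one data structure, `inheritance_rules()`, interpreted by
`evaluate_inheritance()` — a deliberate design so that a revised rule set
(tightened dominance handling, different treatment of affected parents) is a
data edit, not a code change. The defaults are the conventional
single-trio tables:

| model | child | father | mother |
|---|---|---|---|
| autosomal de novo | HET | HOM_REF | HOM_REF |
| autosomal dominant | HET | affected→HET, unaffected→HOM_REF (≥1 affected parent) | same |
| autosomal recessive | HOM_ALT | HET | HET |
| compound het (per gene) | HET at both sites | carrier of exactly one | carrier of the other |
| X-linked de novo | ♀ HET / ♂ hemi | HOM_REF | HOM_REF |
| X-linked dominant | ♀ HET / ♂ hemi | affected→hemi, unaffected→non-carrier | affected→HET, unaffected→non-carrier |
| X-linked recessive | ♂ hemi (♀ HOM_ALT) | ♂ child: HOM_REF (♀ child: hemi) | HET |

Missing genotypes fail a rule in strict mode (the default); permissive mode
treats them as wildcards, which is useful for exploratory passes over
incompletely genotyped trios but inflates hit counts. Optional `min_dp` /
`min_gq` gates demote a stored genotype entry to missing; reconstructed
hom-ref calls (absent entries) pass the gates, since no depth evidence is
stored for them — a strict pipeline should therefore gate upstream at VCF
generation. X-linked models are evaluated only on contigs named `X`/`chrX`,
autosomal models only elsewhere.

Compound heterozygote detection pairs, per gene symbol (transcript field
`SYMBOL` by default), variants where the child is het at both sites, one
site is maternal-only (mother carries it, father hom-ref) and the other
paternal-only. Opposite parental origin makes "neither parent carries both"
automatic; the result is invariant under the input order of variants.

## Case/control comparison

`compare_case_control()` joins the case store with a position-sorted control
VCF on the decomposed key (chrom, pos, ref, alt) and reports per-site alt
allele counts, called-allele totals and frequencies for both cohorts. Per
entry the alt dosage is 1 (het), 2 (hom-alt), or the recorded number of
matching alt alleles for other calls; a missing entry removes the sample's
two alleles from the called total; an absent sample is hom-ref. A site
present in only one cohort is counted as hom-ref across the other cohort —
safe for jointly-called cohorts, *not* for independently called ones, which
is why the convention is surfaced in the `present_in` column rather than
hidden. No test statistic is attached by default; the tool reports counts
and frequencies, with an optional, clearly-labelled two-sided Fisher exact
p-value per record behind `fisher = TRUE`. There is deliberately no
association-testing framework (no covariates, no structure correction).

## The fixture generators

Three deterministic generators make the pipeline testable without external
data, each writing a JSON truth file sufficient for scoring without
re-reading the VCF. A single integer seed drives everything through derived
per-component substreams, so equal parameters give byte-identical files.

* `simulate_multisample_vcf()` — a sorted cohort VCF in any of the three
  annotation dialects. Per sample and site, a call is non-hom-ref with
  probability `alt_fraction` (default 0.3, chosen as a mid-range value that
  exercises both the sparse and dense paths); non-hom-ref calls split
  0.5/0.3/0.2 into het/hom-alt/missing. AC/AN/AF are consistent with the
  emitted genotypes. Sites are biallelic unless `multiallelic_fraction` is
  raised.
* `simulate_trio()` — a trio VCF + PED with planted inheritance patterns.
  Background sites are drawn only from genotype patterns that satisfy none
  of the seven rule tables (child hom-ref; all three het; all three
  hom-alt), so planted-truth recovery is exact by construction. The PED
  encodes an affected child; the father is additionally affected for
  autosomal-dominant plants and the mother for X-linked-dominant plants
  (the two dominant models need contradictory parent statuses and must be
  generated in separate fixtures); the child is male iff X-linked-recessive
  plants are requested. Male X genotypes are written haploid to exercise
  hemizygous normalization.
* `simulate_case_control()` — paired cohort VCFs over a shared site list,
  Hardy–Weinberg genotypes with no missing calls, base frequencies uniform
  on [0.05, 0.5], and a frequency shift of `delta` at `delta_sites` sites;
  the truth records the exact realized counts.

None of this emulates linkage disequilibrium, realistic site-frequency
spectra, sequencing error, or annotation noise. Passing tests therefore
demonstrate that the *rule logic and accounting* are correct, not that the
tool's filters are clinically calibrated on real data.

## Numerical and design choices

* Chunked parallel ingest splits the file into balanced contiguous
  line-range chunks (sizes differ by at most one line) rather than
  per-contig pieces, because contigs are badly unbalanced; chunks are
  re-assembled in order, so the store content is independent of the worker
  count — asserted byte-for-byte in the tests.
* Coordinates are 1-based fully-closed, exactly as in the VCF `POS` column.
* A monomorphic line (`ALT="."`) is skipped and counted as a warning.
* The embedded store persists documents as NDJSON plus JSON artifacts
  (schema, mapping, UI config, flags) under one index directory; the store
  API is a contract (create / bulk load / filtered scan with nested-scope
  semantics) so an external search-server backend could be swapped in
  behind it.
* The null-difference check for the case/control generator uses a
  continuity-corrected two-proportion bound: with 2×100 samples the allele
  frequency difference lives on a 1/200 lattice, and the uncorrected normal
  bound is anti-conservative at exactly this granularity.
* Problem sizes used by the built-in property checks: 10,000 variants × 20
  samples for the parallel-identity check, a 5,000-document store for the
  200-query oracle-equivalence check, 2,000 background variants per planted
  trio fixture, and 500 sites × 100+100 samples × 10 seeds for the
  case/control null check — large enough for the properties to bite, small
  enough to run comfortably on a laptop.

## Worked example

```{r example, eval = FALSE}
library(varscout)

fx <- simulate_multisample_vcf(1000, 8, "vep", seed = 42)
schema <- infer_schema(fx$vcf_path)
store  <- create_index(schema, index_dir = "my_index")
ingest_vcf(fx$vcf_path, store, n_workers = 4)

q <- vs_query(
  attributes = c("CHROM", "POS", "REF", "ALT", "IMPACT", "SYMBOL"),
  filters = list(
    filter_spec("dbsnp_id", "not_exists"),
    filter_spec("IMPACT", "in", "HIGH"),
    filter_spec("FILTER", "eq", "PASS")))
res <- execute(validate_query(q, schema), store)
head(res$rows)
export_csv(validate_query(q, schema), store, "novel_high_impact.csv")
```

## Known limitations

* One trio (plus siblings in principle, but the analyses derive a single
  trio) per pedigree; no multi-family batch mode.
* No re-annotation, no structural variants, no breakend notation.
* The store is in-memory at query time; desk-scale cohorts (up to a few
  hundred thousand documents) are the target, not population biobanks.
* Case/control absence-as-hom-ref is only sound for jointly-called cohorts.
* `Number=R` FORMAT fields are stored as text rather than split per allele.
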