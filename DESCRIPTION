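Package: varscout
Title: Exploration, Mendelian Filtering and Case/Control Comparison of
    Annotated Multi-Sample VCF Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Parses multi-sample VCF files annotated with VEP (nested CSQ
    transcript consequences), Annovar, or generic key=value INFO attributes
    into a sparse nested document store, optionally splitting the file into
    balanced chunks parsed in parallel. Provides a scoped include/exclude
    filter query engine with attribute projection, display capping and CSV
    export; pedigree-driven Mendelian inheritance analyses (autosomal and
    X-linked de novo, dominant and recessive, plus compound heterozygote
    detection); case/control allele-distribution comparison between two
    cohorts matched by site and allele; deterministic synthetic fixture
    generators with machine-readable truth files; and a command-line entry
    point wrapping all of the above.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
RoxygenNote: 7.3.3
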