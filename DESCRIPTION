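Package: wescorr
Title: Genotype-Phenotype Correlation Scoring for Whole-Exome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for exome-cohort variant interpretation:
    quality/frequency/annotation filtering of called variants, Tier-1/Tier-2
    consequence classification, inheritance-aware genotype-phenotype
    correlation scoring (Yes/No/Cannot-assess), secondary-findings gene-panel
    subsetting with per-person burden statistics and a self-implemented
    Fisher's exact test, and a deterministic synthetic-cohort generator so
    every stage can be exercised and verified without access to protected
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    stringr,
    readr,
    rlang,
    jsonlite,
    stats,
    utils,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
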