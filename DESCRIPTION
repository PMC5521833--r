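Package: pathmed
Title: Path-Model Mediation Analysis for Genotype, Fatty-Acid and Blood
    Pressure Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Recursive linear path models (structural equation models on
    observed variables) fitted by maximum likelihood on the covariance
    structure, with standardized direct, indirect and total effect
    decomposition, delta-method and bootstrap inference for mediated
    effects, Benjamini-Hochberg false discovery rate control, and fit
    indices (chi-square, CFI, RMSEA). Includes genotype quality control
    (additive coding, minor allele frequency, Hardy-Weinberg tests,
    call-rate filtering), derived phenotypes for pediatric cohorts
    (blood-pressure reading consolidation, LMS and mean-SD reference
    z-scores, blood-pressure classification, BMI, delta-5 desaturase
    index), a seeded synthetic-cohort generator with ground-truth effect
    ledgers, and an end-to-end analysis pipeline for SNP -> fatty acid ->
    BMI -> blood pressure mediation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    numDeriv,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    readr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
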