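Package: metabopress
Title: Serum Metabolite and Blood Pressure Association Analysis for CKD Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A replication-design pipeline for untargeted serum metabolomics
    studies of blood pressure in chronic kidney disease (CKD) cohorts.
    Implements blood-pressure stage coding, pivot-based correlation-clustering
    feature reduction for collinear LC-MS features, per-feature linear
    regression with CKD-stage adjustment across discovery, validation and
    pooled cohorts with Benjamini-Hochberg correction, cumulative adjusted
    R-squared accounting, ROC evaluation of dichotomized blood pressure, and a
    leave-one-feature-out neural-network importance procedure. Ships a
    synthetic two-cohort generator with block-collinear features and planted
    effects so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
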