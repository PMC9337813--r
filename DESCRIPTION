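Package: metabosvd
Title: Metabolome-Wide Association Analysis for Cerebral Small Vessel Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for serum metabolomics studies of
    cerebral small vessel disease severity. Provides pooled-QC LOESS
    correction of run-order and batch intensity drift, feature quality
    filtering (pooled-QC relative standard deviation, dilution-series
    linearity, study-to-QC variance ratio), generalized log transformation
    and autoscaling, and metabolome-wide association models: cross-sectional
    linear and logistic regression, annualized-change models, and Cox
    proportional hazards for incident dementia, with Benjamini-Hochberg
    false discovery rate control and stratified sensitivity analyses. A
    synthetic-data module generates analytical runs (pooled QC, dilution
    series, multiplicative drift, batch offsets) and two-cohort clinical
    populations with planted effects so the whole pipeline is testable
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
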