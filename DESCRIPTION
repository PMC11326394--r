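Package: acuityssm
Title: ICU Acuity State Prediction with Selective State-Space Sequence Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computable phenotyping of intensive-care acuity states
    (discharge, stable, unstable, deceased) from life-sustaining-therapy
    intervals, triplet encoding of irregular clinical event streams without
    imputation, a selective state-space (Mamba-style) sequence classifier
    with nine prediction heads, deterministic acuity decision logic,
    step- and episode-level alarm evaluation with precision-targeted
    thresholds, isotonic probability calibration, SOFA baselines,
    integrated-gradients attribution, and a seeded synthetic ICU cohort
    generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    readr,
    yaml,
    optparse,
    withr
Config/testthat/edition: 3
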