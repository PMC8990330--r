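Package: actiphen
Title: Actigraphy Digital Phenotyping of SSRI-Associated Movement Patterns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects selective serotonin reuptake inhibitor (SSRI) exposure
    from week-long minute-level accelerometer counts. Provides a synthetic
    actigraphy cohort generator with plantable effect sizes, NHANES-style
    ingestion (activity records, medication tables, PHQ-9 scores),
    Savitzky-Golay smoothing, day-by-hour-by-minute tensor reshaping and
    per-minute standardization, stratified cross-validation with class
    weighting, a Daubechies-wavelet-feature logistic baseline, a
    convolutional LSTM classifier with optional depression-score fusion,
    integrated-gradient temporal attributions, descriptive rest-activity
    statistics (group means, morning and evening slopes), and evaluation
    metrics (AUC, Youden cut points, confusion rates, balanced accuracy,
    population stability index).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    foreign,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
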