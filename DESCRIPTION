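Package: fhrscreen
Title: Antepartum Fetal Heart Rate Screening via Empirical Mode
    Decomposition and Support Vector Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies 4 Hz antepartum fetal heart rate (FHR) traces as
    'normal' or 'at risk'. Traces are cleaned of missing beats and spike
    artifacts, decomposed into intrinsic mode functions by empirical mode
    decomposition (EMD) with a sum-of-difference stopping rule, denoised by
    discarding the low-order noise modes identified with a partial-sum
    t-test, and summarised as intrinsic-mode-function standard deviations.
    A class-weighted soft-margin support vector machine with a radial basis
    function kernel performs the classification, and a full evaluation
    battery (stratified k-fold cross-validation, sensitivity, specificity,
    geometric mean, Cohen's kappa with confidence interval) is provided,
    together with a synthetic FHR generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    e1071,
    dplyr,
    generics,
    tibble,
    rlang,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    purrr,
    optparse
Config/testthat/edition: 3
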