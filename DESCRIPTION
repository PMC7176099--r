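Package: replicast
Title: Probabilistic Forecasting and Evaluation of Replication Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form predictive distributions of replication effect
    estimates on the Fisher-z scale under a hierarchical effect-size model
    with between-study heterogeneity, using either a flat prior or an
    empirical-Bayes sceptical (g-type) prior with evidence-based shrinkage.
    Includes proper scoring rules for normal and binary forecasts (logarithmic,
    quadratic, CRPS, Brier), calibration tests (Spiegelhalter z, score-based
    z and regression tests, PIT uniformity, calibration slope), discrimination
    (AUC), chi-squared observed-versus-expected comparisons, prediction
    intervals, replication probabilities, sample-size planning, and a
    synthetic replication-project generator with optional significance
    selection of original studies.
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
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
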