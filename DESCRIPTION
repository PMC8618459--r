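Package: readmitrisk
Title: Daily Hospital-Readmission Risk Trajectories from Mobile Sensing Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the day-by-day probability of hospital readmission after
    surgical discharge. Administrative risk scores (LACE index, HOSPITAL
    score) are mapped to an initial probability and expanded into a 60-day
    risk trajectory by parametric functions (linear, exponential,
    logarithmic, weighted linear). A feature pipeline turns daily
    smartphone/wearable feature tables into model-ready panels (deviation
    features, missingness filters, moving-average imputation, min-max
    normalization). An autoregressive two-layer LSTM trained
    leave-one-patient-out predicts the next day's risk, optionally fed the
    previous day's actual or predicted probability; classic per-day
    regressors (multiple linear regression, CART, support-vector
    regression) serve as baselines. Competing models are ranked by a
    composite point system over twelve MSE/covariance submetrics. A
    synthetic-cohort generator emulates the statistical structure of the
    original study data so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    quadprog,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
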