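Package: sccscore
Title: Self-Supervised Detection of Serious Clinical Complications from
    Wearable Vital-Sign Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for anomaly detection in continuous 1 Hz wearable
    recordings of vital signs and physical activity during intensive
    medical treatment.  The package simulates inpatient/outpatient
    wearable cohorts with ground-truth complication events, segments
    recordings into hours, annotates regular and non-regular periods
    around documented complications, trains a 1-D residual convolutional
    encoder with a temperature-scaled contrastive (NT-Xent) objective,
    computes nearest-neighbour cosine-similarity SCC-Scores against
    patient-specific or cohort-wide reference sets, applies an empirical
    null-distribution detection test, and evaluates detection and
    prediction performance (AUROC with cross-validation and bootstrap
    errors, Youden cut-points, specificity at high sensitivity, group
    t-tests with Bonferroni correction, z-score trajectories and
    event-anchored score curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
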