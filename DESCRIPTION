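Package: strokehr
Title: Stroke Risk Prediction from Longitudinal Health Records
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for predicting a first stroke diagnosis
    within one year from longitudinal electronic health records: a synthetic
    EHR generator with a controllable planted stroke-hazard signal, matched
    case/control cohort construction with grouped train/validation/test
    splitting, temporal feature encoding of diagnosis and exam histories,
    an ICD-10 autoencoder embedding, three neural predictors (recurrent,
    dense, and dual-input) trained with an imbalance-penalizing surrogate
    loss, and ROC/AUC evaluation with stratified bootstrap confidence
    intervals and feature-ablation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
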