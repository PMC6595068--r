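Package: readmitr
Title: Timeline-Aware 30-Day Readmission Modelling on Hospitalization Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A study pipeline for 30-day all-cause readmission prediction
    after heart-failure hospitalization from administrative claims.
    Provides a synthetic claims generator with a controllable
    history-dependent readmission mechanism, patient timeline construction
    and 30-day labeling, per-event feature encoding, four timeline-aware
    training objectives, a model zoo (regularized logistic regression,
    multilayer perceptron, convolutional networks, recurrent networks with
    optional scheduled sampling, and linear-chain conditional random field
    hybrids with exact forward-backward/Viterbi inference), a stratified
    cross-validation harness with influence-function confidence intervals
    for the cross-validated AUC and Youden-index cutoffs, and
    feature-importance analyses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
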