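Package: calens
Title: Calibrated Loss Functions, Segmentation Losses and Model Ensembles
    for Multi-Class Medical Image Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Batch-level implementations of calibration-aware classification
    losses (entropy-regularized cross-entropy, calibrated negative entropy,
    calibrated Kullback-Leibler, calibrated focal and calibrated Hinge losses),
    the five standard binary segmentation losses (BCE, weighted BCE-Dice,
    focal, Tversky, focal Tversky), prediction-level and model-level ensemble
    procedures (majority voting, simple and weighted averaging with
    simplex-constrained log-loss weight optimization, stacking, feature
    fusion, bitwise-AND mask fusion), and the matching evaluation metrics
    including the multi-class Matthews correlation coefficient with an exact
    Clopper-Pearson interval. Ships a seeded synthetic-data module emulating
    class-imbalanced chest-radiograph-like image/mask/label triples and
    calibration-controlled prediction matrices, a mask-driven cropping and
    contrast-enhancement pipeline, and a tiny encoder-decoder training engine
    for desk-scale experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    png,
    stats,
    utils
Suggests:
    glmnet,
    pROC,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
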