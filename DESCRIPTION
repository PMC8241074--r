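Package: adaptivenet
Title: Recurrent Encoding of Heterogeneous Clinical Event Histories for
    Rheumatoid Arthritis Disease-Activity Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements AdaptiveNet, a recurrent neural architecture that
    encodes variable-length, heterogeneous clinical event histories (visits
    and medication adjustments) into a fixed-length latent representation
    for next-visit prediction of rheumatoid-arthritis disease activity
    (DAS28-BSR), by classification (active disease vs remission) and
    regression (numeric score change).  Ships a seeded synthetic registry
    generator emulating the structure of longitudinal RA registries,
    cohort construction with leakage-safe patient-level cross-validation,
    classical baselines (random forest, linear/logistic regression, RBF
    support vector machine), and the full evaluation machinery (confusion
    metrics, ROC/AUC, Welch's t-test across folds, subgroup tables,
    impurity-based feature importance).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    jsonlite,
    ranger,
    e1071
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
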