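Package: prnet
Title: Partial Response Networks for Interpretable Clinical Risk Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits self-explaining neural classifiers for tabular clinical
    data by the partial response network (PRN) method. A black-box
    multilayer perceptron is decomposed by a median-anchored functional
    ANOVA into univariate and bivariate partial responses; an L1-penalized
    logistic regression over those responses selects a sparse generalized
    additive model; and a modular network initialized to reproduce the
    selected model exactly is retrained and re-decomposed to give the final
    PRN-Lasso. Includes a transplant-registry-like synthetic data
    generator with known ground truth, median-anchored standardization,
    stacked multiple imputation, per-patient additive explanations,
    nomogram export, and the standard validation statistics (AUROC with
    DeLong confidence intervals and paired comparison, Hosmer-Lemeshow
    calibration, expected/observed ratio, calibration-in-the-large).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    ggplot2,
    generics,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
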