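Package: hifit
Title: High-Dimensional Biomarker Screening and Permutation Feature
    Importance Testing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Hybrid marginal feature screening for high-dimensional omics
    data that fuses a polynomial generalized-linear-model utility with a
    kernel partial correlation coefficient through isolation-forest anomaly
    scores, selects the score cutoff by set-level permutation importance
    over a candidate grid, and refines the screened list with a
    permutation-based feature importance test under support vector machine,
    random forest, gradient boosting, or ensemble neural network models.
    Includes generators for block-correlated simulation designs and a
    benchmark harness for selection and prediction metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    nnet,
    pROC,
    ranger,
    stats,
    tibble,
    utils,
    withr,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
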