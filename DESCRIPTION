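Package: hingeseek
Title: Sequence-Based Analysis and Prediction of Protein Hinge-Bending Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical analysis and prediction of hinge-bending regions in
    protein sequences. Implements the Hinge Index amino-acid propensity
    statistic with exact hypergeometric significance testing, kernel logistic
    regression over sliding-window one-of-n encoded sequences (linear,
    polynomial and radial basis function kernels, trained by iteratively
    reweighted least squares in the dual with approximate leave-one-out
    hyper-parameter tuning), evaluation utilities (ROC/AUROC, precision-recall,
    DeLong's paired AUROC test, sequence-level nested cross-validation),
    primal-weight interpretation of linear and quadratic models, and a
    bootstrap-ensemble per-residue hinge predictor with sequence-identity
    filtered model selection. A configurable generator of synthetic annotated
    sequences supports end-to-end testing without structure-derived data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
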