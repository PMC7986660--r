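Package: labelsimex
Title: Bias Correction for Regression on Cluster-Derived Class Labels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Outcome regression on class labels produced by unsupervised
    clustering is biased by label misclassification. Implements two general
    corrections: the misclassification simulation-extrapolation (mcsimex)
    estimator, including a Cox proportional-hazards extension with jackknife
    and bootstrap variance estimation, and regression calibration via
    posterior class probabilities. Provides estimation of the
    misclassification matrix from fitted clustering models (Monte Carlo and
    out-of-bag bootstrap procedures), real matrix powers via spectral
    decomposition with existence diagnostics, and a simulation engine for
    Monte Carlo bias and coverage studies on Gaussian-mixture data with
    logistic or survival outcomes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    mclust,
    purrr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
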