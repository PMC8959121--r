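Package: fcmkl
Title: Sparse Multiple Kernel Learning for Connectivity-Based Prediction of
    Clinical Scores
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Individualized prediction of cognitive and motor scores from
    seed-based resting-state functional connectivity. Implements the full
    analysis chain: nuisance regression, band-pass filtering, spherical-ROI
    time-series extraction, Fisher-z seed connectivity features, linear
    kernel construction with training-fold centering and normalization,
    sparse (block-L1) multiple kernel learning epsilon-insensitive
    regression with a nested leave-one-out / 5-fold cross-validation,
    permutation significance testing, Meng's Z test for dependent
    correlations, computational kernel-lesion analysis, and a synthetic
    cohort generator with known connectivity-to-behavior ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    kernlab,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
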