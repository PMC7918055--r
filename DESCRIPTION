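Package: emgdecode
Title: Continuous 3-D Hand-Position Decoding from Surface EMG with a
    Recurrent Fuzzy Neural Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting three-dimensional hand position at a
    future time horizon directly from multi-channel surface
    electromyography (EMG). Implements the full offline decoding
    pipeline: linear-envelope EMG preprocessing (detrending, median
    despiking, rectification, 2 Hz zero-phase Butterworth filtering,
    kinematic resampling), overlapping-window time-domain feature
    extraction (MAV, VAR, RMS, WL, IEMG, SSI, SSC), a four-layer
    recurrent fuzzy neural network regressor with Gaussian memberships,
    per-rule recurrent states, clustering-based rule initialisation and
    gradient-descent parameter learning, and cross-validated evaluation
    (NRMSE, Pearson correlation, speed comparisons, prediction-horizon
    sweeps). A synthetic generator produces synchronized EMG and
    kinematics with a configurable electromechanical lead so every stage
    is testable without human-subject recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
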