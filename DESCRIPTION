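Package: eegid
Title: EEG-Based Person Identification Under Escalating Cognitive Load
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation, preprocessing, and classification pipeline for
    closed-set biometric identification from multichannel EEG. Provides a
    synthetic cohort generator with per-subject spectral signatures and
    task-dependent band modulation, zero-phase Butterworth/notch filtering,
    common average re-referencing, sliding-window epoch segmentation,
    z-score normalization, two 1D convolutional neural network variants
    trained with Adam, and a 5-fold cross-validated channel-reduction
    study over scalp regions, including EDF and CSV signal I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
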