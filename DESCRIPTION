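Package: eyewrite
Title: Eye-Writing Trajectory Recognition with a Hybrid 1D CNN-TCN
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognising eye-written characters from two-channel
    (x, y) gaze or electrooculography (EOG) trajectories. Implements a
    signal-conditioning chain (median filter, zero-phase Butterworth low-pass,
    DC blocker), Fourier-domain length normalization of variable-length
    trajectories, initial-point normalization, two trajectory augmentations
    (segmental stochastic scaling distortion and window warping), a hybrid
    one-dimensional CNN plus temporal convolutional network classifier with
    depthwise-pointwise dilated causal convolutions and squeeze-and-excitation
    channel attention, and a leave-one-subject-out evaluation harness with
    exact Wilcoxon signed-rank testing. Includes a seeded synthetic
    eye-writing generator so the full pipeline is testable without any
    external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
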