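Package: sparsacc
Title: Detection of Normal and Slow Saccades by Sparse-Derivative Denoising
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects saccadic eye movements, including pathologically slow
    saccades, in eye-tracking position time-series. Noise is removed by
    minimizing a convex objective that penalizes the L1 norms of the first-
    and third-order differences of the signal (a generalization of total
    variation denoising) via a majorization-minimization algorithm with a
    banded linear solve; saccades are then found by hysteresis velocity
    thresholding with physiological post-processing rules. Includes a
    parametric saccade simulator built on the main-sequence relation between
    peak velocity and amplitude, automatic data-driven setting of the
    regularization parameters, velocity- and dispersion-threshold baseline
    detectors, event-level evaluation metrics, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    optparse,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
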