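Package: iltnmr
Title: Inverse Laplace Transform Analysis of Time-Domain NMR Relaxation Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers relaxation-time distributions from multi-exponential
    time-domain NMR signals (CPMG, inversion recovery, saturation recovery)
    by regularized inversion of the discretized Fredholm model: singular
    value decomposition compression followed by Tikhonov-penalized
    non-negative least squares. Includes signal preprocessing (start-point
    removal, baseline offset correction, first-value normalization), a
    simulator that integrates log-Gaussian relaxation-time distributions
    into noisy synthetic signals, peak detection and ground-truth comparison
    metrics, plain-text table input/output, and a command-line interface
    for batch processing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    generics,
    withr,
    stats,
    utils
Suggests:
    pracma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
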