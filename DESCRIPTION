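Package: cardiostager
Title: Sleep Staging from Instantaneous Heart Rate with Dilated
    Convolutional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for four-class sleep staging (wake, light, deep, REM)
    from single-lead ECG. Implements Pan-Tompkins R-peak detection,
    inter-beat-interval filtering and instantaneous-heart-rate (IHR)
    extraction, a fully convolutional per-epoch staging network built
    from a patch-wise local feature extractor and dilated temporal
    convolution blocks, masked cross-entropy training, epoch-wise
    agreement metrics (accuracy, Cohen's kappa, confusion matrices),
    hypnogram-derived sleep metrics, and covariate statistics
    (rank tests with Bonferroni control and sequentially adjusted
    least-squares regression). A stage-conditioned synthetic-data
    generator produces overnight hypnograms, cardiac interval series,
    ECG waveforms and covariate-structured cohorts so the whole
    pipeline can be exercised without access-restricted
    polysomnography datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
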