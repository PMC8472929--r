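Package: gasfnet
Title: Arrhythmia Classification from Gramian Angular Field ECG Images with an
    Improved Residual Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end single-lead ECG rhythm classification. Fixed-length ECG
    segments are encoded as Gramian Angular Summation Field (GASF) images and
    classified with a modified ResNet-50: five auxiliary 1x1-convolution
    shortcut groups, downsampling relocated to the 3x3 convolutions with
    average-pool bypasses, pre-activation residual blocks, and the SELU
    self-normalizing activation. Includes readers for WFDB and CSV records,
    stratified splitting, a deterministic CPU training loop with Adam,
    confusion-matrix evaluation (precision, sensitivity, specificity, F1,
    accuracy), and a seedable synthetic generator for seven rhythm classes
    (AF, AT, N, PAC, PVC, SBR, VT) so the whole pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
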