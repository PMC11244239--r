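Package: strokeEEG
Title: EEG Connectivity and Complexity Features with a
    Squeeze-and-Excitation CNN for Ischemic Stroke Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for detecting acute ischemic stroke from 19-channel
    scalp EEG. Implements correlation-weighted Phase Lag Index (cwPLI)
    functional-connectivity matrices from Hilbert-transform instantaneous
    phases, per-channel Sample Entropy, fusion of both feature families
    into channel-by-channel maps rendered as RGB images, and a compact
    VGG-style convolutional classifier augmented with squeeze-and-excitation
    channel attention, trained by stochastic gradient descent and evaluated
    with subject-level stratified cross-validation (accuracy, sensitivity,
    specificity, ROC/AUC). Includes a two-class synthetic EEG generator with
    controllable inter-channel phase coupling and signal complexity, EDF
    import/export, and zero-phase Butterworth preprocessing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    Rcpp,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
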