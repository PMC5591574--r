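Package: eyescript
Title: Reconstruction and Recognition of EOG Eye-Written Digits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for turning multi-channel electrooculogram (EOG) recordings
    of eye-written Arabic digits into classified symbols. The pipeline covers
    downsampling and median filtering, automatic blink detection and removal,
    baseline and drift correction, bipolar derivation, saccade detection with a
    Haar continuous wavelet transform, reconstruction of normalized 2-D gaze
    traces with calibration-free removal of horizontal-to-vertical crosstalk,
    and classification against canonical digit templates with dynamic time
    warping (DTW), dynamic positional warping (DPW), and their combinations
    with a support vector machine over normalized-dissimilarity features.
    A ground-truth-annotated synthetic EOG simulator makes every stage
    testable without recorded data, and leave-one-subject-out evaluation
    reports per-participant and per-digit performance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
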