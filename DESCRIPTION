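Package: spindlr
Title: Sleep Spindle Detection in Single-Channel EEG with a Slim 1D U-Net
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects sleep spindles (11-16 Hz sigma-band bursts of at least
    0.5 s) in single-channel N2-sleep EEG. Implements a slim fully
    convolutional 1D U-Net that maps a z-scored 100 Hz segment to per-sample
    spindle probabilities, trained with a generalized dice loss, Adam, and
    by-subject k-fold cross-validation with F1-based early stopping.
    Includes MODA-compatible signal conditioning (zero-phase Butterworth
    band-pass, downsampling to 100 Hz, per-segment z-transform),
    moving-average post-processing that turns probability tracks into event
    annotations, an event-level evaluation framework (overlap-based matching,
    recall/precision/F1, F1 integrated over overlap thresholds, by-subject
    spindle density and duration statistics), and a synthetic EEG generator
    that plants ground-truth sigma bursts in 1/f background so the whole
    pipeline is testable without access to polysomnography archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
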