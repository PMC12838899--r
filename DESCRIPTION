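Package: seizewin
Title: Near-Real-Time EEG Seizure Detection with Wavelet Features and
    Bidirectional LSTM Networks
Version: 0.1.0
Authors@R:
    person("Seizewin", "Developers", email = "seizewin@example.org",
           role = c("aut", "cre"))
Description: A windowed EEG seizure-detection toolkit: multichannel
    recordings are cut into non-overlapping 0.5 second frames augmented
    with an arithmetic-mean channel and single-level discrete wavelet
    coefficients, balanced into equal-duration ictal/interictal segments,
    packetized into 5 minute training sequences, and classified with a
    bidirectional long short-term memory (BiLSTM) network implemented in
    compiled code.  Includes event-level evaluation (detection delay,
    undetected-seizure accounting, composite scoring under configurable
    weighting schemes), electrode-reduction experiments via correlation
    ranking and Shapley channel attribution, outlier-aware retraining,
    a causal streaming-inference harness with per-stage timing, and a
    synthetic EEG cohort generator so the full pipeline runs without any
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
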