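Package: nervedecodr
Title: Temporal Feature Extraction and Finger-Movement Decoding for
    Multi-Channel Peripheral Nerve Recordings
Version: 0.1.0
Authors@R:
    person("nervedecodr", "developers", email = "nervedecodr@example.org",
           role = c("aut", "cre"))
Description: A pseudo-online motor-decoding toolkit for multi-channel
    peripheral nerve (or EMG-like) recordings. Provides band-limiting and
    sliding-window trial cutting, a set of fourteen classic time-domain
    features computed over overlapped 100 ms windows that compress a
    16-channel stream more than 40-fold, two decoding strategies (one-step
    direct regression of all finger joints, and two-step classify-then-
    regress with per-joint model gating), shallow convolutional/recurrent
    neural decoders plus support-vector, random-forest and multilayer-
    perceptron baselines implemented natively, evaluation metrics (balanced
    accuracy, F1, MSE, variance accounted for), leakage-free splitting of
    overlapped windows, and a synthetic-session simulator with time-locked
    glove ground truth so the full pipeline is testable without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    rlang,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
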