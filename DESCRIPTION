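Package: scalerp
Title: Unmixing Fixed-Time and Scaled-Time Components in Continuous EEG
Version: 0.1.0
Authors@R: person("scalerp", "developers", role = c("aut", "cre"),
    email = "scalerp@example.org")
Description: Regression-ERP (rERP) estimation of event-related EEG waveforms
    from continuous recordings, extended with a variable-duration
    "scaled-time" regressor whose temporal support stretches or compresses
    to span the interval between two events (e.g. cue and response).
    Provides a ground-truth simulator for interval-timing experiments,
    sparse convolutional design matrices built from stick functions,
    penalized least squares with a first-derivative Tikhonov penalty and
    cross-validated regularization strength, variance inflation factor
    diagnostics, conventional epoch-based ERPs, a temporal-scaling index,
    spatiotemporal cluster-based sign-flip permutation tests, a PCA-based
    latency analysis, and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
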