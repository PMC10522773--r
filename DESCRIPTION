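Package: ertrial
Title: Single-Trial Latency Estimation and Realignment for Event-Related Potentials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the trial-to-trial latency variability of
    event-related potential (ERP) components such as the P300 and N400.
    Provides a ground-truth-labelled simulator that injects a half-sine
    component with per-subject latency jitter into surrogate background EEG
    at calibrated signal-to-noise ratios; averaging-based latency measures
    (peak and fractional-area); single-trial template-matching estimators
    (multichannel cross-correlation with optional Woody iteration,
    multichannel dynamic time warping, a spatiotemporal LCMV beamformer, and
    ICA-based subspace matching); two neural-network latency regressors (a
    depthwise-separable convolutional network and a convolutional LSTM on a
    5x5 electrode grid) implemented natively with Adam training; and a
    subject-grouped cross-validated evaluation pipeline scoring estimators
    by latency error and by fidelity of the realigned component's shape and
    topography.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    ica,
    jsonlite,
    rhdf5,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
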