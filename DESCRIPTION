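Package: myoprop
Title: Regression-Based Proportional Myoelectric Control of a Two
    Degree-of-Freedom Hand-Wrist Prosthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for regression-based, simultaneous and proportional
    two degree-of-freedom (hand open-close, wrist pronation-supination)
    myoelectric prosthesis control from multichannel surface EMG.
    Implements a causal five-stage EMG amplitude (EMGsigma) estimator,
    calibration of a linear EMGsigma-force model by singular-value
    truncated pseudo-inverse least squares, backward stepwise electrode
    selection, resting thresholds with fixed-ratio co-activation gating,
    a conventional two-site sequential controller with co-contraction
    mode switching, a virtual hand-wrist prosthesis plant, and a seeded
    synthetic surface-EMG session generator with known ground-truth
    efforts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), yaml
Config/testthat/edition: 3
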