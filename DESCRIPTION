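Package: sistand
Title: Two-Stage Sit-to-Stand Transition Detection from Orthosis-Mounted Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the initiation of sit-to-stand (SiSt) posture transitions
    from a 14-channel sensor array mounted on a knee-ankle-foot orthosis
    (accelerometers, gyroscopes, joint potentiometers, insole force sensors).
    Implements the full recognition pipeline: translation-invariant wavelet
    denoising, 0.2 s epoching, knee-angle-based automatic annotation,
    154-dimensional per-epoch feature extraction with lagged-epoch
    concatenation, minimum-redundancy-maximum-relevance (mRMR) ranking
    followed by wrapper forward feature selection, extreme learning machine
    (ELM) and multilayer perceptron (MLP) classifiers, and a two-stage
    cascade (sitting detector gating a transition detector) designed to
    eliminate false positives. Ships a seeded synthetic orthosis-signal
    simulator emulating a 10-subject, 34-trial activity protocol, plus an
    epoch-, transition- and detection-time-level evaluation harness with
    leave-one-subject-out cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    readr,
    truncnorm,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
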