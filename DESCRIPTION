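Package: pigdgan
Title: Scoring Parkinsonian Gait Severity from a Lumbar Wearable with
    Adversarially Trained Convolutional Regressors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the postural instability and gait disorder (PIGD)
    sub-score of the motor examination of the Unified Parkinson's Disease
    Rating Scale from a single lumbar inertial sensor. Walk recordings are
    segmented by gyroscope-based turn detection, high-pass filtered, and
    converted to fixed-size log spectra; a small one-dimensional
    convolutional regressor is then trained either plainly (CNN) or
    adversarially against a fully connected generator (GAN) with a
    paired-visit loss that rewards correct within-subject ON/OFF ordering
    of medication states. Includes a synthetic gait-cohort simulator so the
    whole pipeline runs offline, plus evaluation utilities for ON/OFF
    discrimination accuracy and agreement with clinician scores.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
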