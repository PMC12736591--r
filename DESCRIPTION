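Package: airspiral
Title: Wearable-IMU Analysis of Mid-Air Spiral Drawing for Early Parkinson's Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: End-to-end pipeline for detecting early Parkinson's disease from
    six-axis wristband recordings of mid-air Archimedean-spiral tracing.
    Simulates labelled healthy and Parkinsonian cohorts with ground-truth
    attitude and tremor-burst annotations, estimates roll/pitch attitude from
    accelerometer and gyroscope streams with a two-state Kalman filter,
    segments and min-max normalizes the angle traces into fixed-length
    windows, trains a family of attention-augmented stacked-LSTM classifiers
    (LAFNet and variants), and produces attention-interpretability reports
    (normalized temporal attention maps, smoothed overlays, channel-wise
    importance percentages).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
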