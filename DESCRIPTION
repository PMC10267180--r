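Package: phytostress
Title: Detecting Nitrogen-Deficiency Stress from Plant Electrophysiology
Version: 0.1.0
Authors@R:
    person("Phytostress", "Developers", email = "maintainer@phytostress.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting abiotic stress (nitrogen
    deficiency) in greenhouse plants from raw univariate electrophysiological
    voltage recordings. Provides a synthetic multi-plant cohort generator,
    signal conditioning (powerline notch filtering, rolling-median
    simplification with decimation, windowing, normalization), four
    one-dimensional neural-network window classifiers (MLP, FCN, ResNet and a
    convolutional encoder with time-wise attention), causal fusion of
    consecutive prediction confidences, plant-wise held-out evaluation and
    leave-one-out cross-validation, early stress-onset detection on confidence
    traces, and a handcrafted-feature gradient-boosted-tree baseline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    rhdf5,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
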