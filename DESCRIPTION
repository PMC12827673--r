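Package: amanet
Title: Data-Augmented Multi-Scale Temporal Attention Networks for Motor-Imagery EEG
Version: 0.1.0
Authors@R:
    person("BCI", "Tools", email = "bci-tools@example.org", role = c("aut", "cre"))
Description: Decoding pipeline for motor-imagery electroencephalography (EEG):
    sliding-window data augmentation, common spatial pattern (CSP) filtering via
    generalized eigendecomposition, and a compact convolutional classifier with
    multi-scale temporal convolutions, efficient channel attention (ECA), and
    depthwise separable fusion. Includes a synthetic motor-imagery generator
    with known class structure, a leakage-safe cross-validation harness with
    Cohen's kappa and confusion-matrix reporting, ablation presets, parameter
    sweep utilities, and a command-line entry point. The network is implemented
    in base R with an internal reverse-mode gradient engine; no external deep
    learning framework is required.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
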