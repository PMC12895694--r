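Package: psvrcap
Title: Periodic Support Vector Regression Decoding and Working-Memory
    Capacity Simulation for Multivoxel Orientation Patterns
Version: 1.0.0
Authors@R:
    person("Mira", "Holzer", email = "mira.holzer@posteo.net", role = c("aut", "cre"))
Description: Tools to simulate multivoxel fMRI-like orientation patterns under
    varying working-memory load and capacity (cosine-basis voxel tuning,
    additive two-item superposition, Gaussian noise), to decode orientations
    continuously with a periodic support vector regression (independent
    radial-basis-function SVRs on the sine and cosine labels of the circular
    orientation, four-quadrant angle reconstruction) scored as
    feature-continuous accuracy, and to run the accompanying group-level
    inference: circular recall precision, paired comparisons, Pearson and
    partial correlations, cluster-based sign-permutation tests on temporal
    generalization matrices, and a dynamic-cluster criterion. A capacity
    experiment driver sweeps signal strengths and compares Load 1 against
    Load 2 decoding under capacity-two (superposed) and capacity-one (one
    random item) regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
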