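Package: multilocbn
Title: Multi-Location Protein Subcellular Localization with Bayesian
    Network Classifiers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the (possibly multiple) subcellular locations of
    proteins from precomputed numeric feature tables using a collection of
    per-location Bayesian network classifiers that model inter-dependencies
    among locations. Each classifier's network structure is learned by
    greedy hill climbing driven by the conditional log likelihood of the
    target location indicator given the features and support-vector-machine
    estimates of the other location indicators. Includes minimal-entropy
    (MDL-stopped) feature discretization adapted to multi-labeled instances,
    the full set of adapted multi-label evaluation measures with repeated
    stratified cross-validation, and a seeded synthetic-data generator with
    controllable inter-label dependency structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
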