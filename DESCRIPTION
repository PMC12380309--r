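Package: cliffhmm
Title: Covariate-Modulated Hidden Markov Models for Rodent Visual-Cliff Locomotion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing mouse locomotion in a circular visual-cliff arena
    with a three-state hidden Markov model whose transition probabilities and
    angular concentrations depend on logistic spatial-influence functions of the
    distances to the cliff boundary, the arena edge, and the arena centre. Covers
    reading DeepLabCut-style pose-tracking tables, arena calibration and coordinate
    standardisation, step-length/turning-angle feature extraction, maximum a
    posteriori fitting with Laplace uncertainty (optional Metropolis refinement and
    partial pooling across animals), state decoding, stationary-state profiles
    along synthetic paths, the cliff-effect statistic, and a generative simulator
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    MASS,
    metafor,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
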