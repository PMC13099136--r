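Package: stategen
Title: Hidden-State Generalization Analysis for Neural Populations in Odor Sequence Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for testing whether neural populations compress
    ("generalize over") task positions that share a hidden state in figure-8
    odor sequence tasks. Provides epoch-aligned firing-rate extraction from
    spike trains, per-unit sequence- and position-selectivity statistics,
    pseudoensemble decoding with label-shuffled permutation nulls,
    cross-sequence generalization decoding, canonical polyadic (CP/TCA)
    tensor decomposition with multi-restart stability diagnostics, and
    mutual information of trial factors. Includes a synthetic session
    generator with inhomogeneous-Poisson spiking and planted "compressed"
    and "differentiated" population structure for end-to-end validation.
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
    jsonlite,
    e1071
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
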