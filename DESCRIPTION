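Package: releaseflow
Title: Circuit-Theory Prediction of Animal Movement from Translocation Release Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for predicting where translocated soaring birds
    will move after release. Filters flight telemetry (fix quality, ground-speed
    window, offshore and near-release-site exclusions, daily thinning), builds a
    landscape conductance surface with a maximum-entropy presence-background
    model (linear and quadratic features, clamping, 5-fold cross-validation,
    AIC-based selection), converts the surface to a resistor lattice and solves
    source-to-ground-ring electrical circuits for direction-neutral current
    maps, calibrates current against movement points with the continuous Boyce
    index and reverse cumulative frequency curves, and extracts least-cost
    linkage networks between core habitat patches. Includes a synthetic
    landscape and telemetry generator so the whole pipeline is reproducible
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    MASS,
    withr
Config/testthat/edition: 3
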