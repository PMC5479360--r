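Package: lvstiff
Title: Passive Left-Ventricular Myocardial Stiffness Estimation from
    Volume-Driven Diastolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Non-invasive estimation of passive left-ventricular myocardial
    stiffness from motion data. Implements idealized truncated-ellipsoid LV
    meshes with rule-based transmural fibre fields, an incompressible
    hyperelastic finite-element solver (reduced Holzapfel-Ogden law,
    quadratic-linear mixed elements) driven by cavity volume through a scalar
    Lagrange multiplier with relaxed basal and epicardial boundary conditions,
    parameter-ratio sweeps with refinement and rescaling of stiffness by an
    estimated end-diastolic pressure, identifiability and sensitivity
    diagnostics, clinical LV metrics with group comparison, and a synthetic
    subject generator with known ground truth for verification studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils,
    xml2,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
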