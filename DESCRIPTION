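Package: corneafem
Title: Patient-Specific Corneal Finite-Element Simulation of Pterygium Traction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Builds patient-specific finite-element models of the human cornea
    (plus a scleral rim) from anterior/posterior elevation tomography, recovers
    the stress-free configuration under intraocular pressure, simulates the
    tangential limbus-ward pulling force of a retracting pterygium with an
    anisotropic fiber-reinforced hyperelastic tissue model, and quantifies the
    induced corneal shape change: sagittal curvature and keratometry,
    astigmatism cylinder and axis, best-fit-sphere elevation, pachymetry,
    anterior corneal wavefront aberrations, and region-averaged tissue stress
    and strain. Includes a synthetic Scheimpflug-like tomography generator
    (biconic/toric surfaces with a parameterized nasal pterygium footprint) so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
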