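Package: propellr
Title: Molecular Propeller Effect: Theory, Rotational Brownian Dynamics and
    Enantiomeric Separation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the propulsion of dipolar chiral molecules driven by a
    rotating electric field (the molecular propeller effect) and the resulting
    enantiomeric separation. Provides the closed-form theory (Boltzmann
    orientation statistics, responding fraction, escape and effective rotation
    frequencies, angular correction factor, propulsion velocity), an overdamped
    rotational Brownian dynamics simulator with built-in rotational-to-
    translational coupling, trajectory estimators for rotational diffusion and
    coupling length, a one-dimensional drift-diffusion model of enantiomeric
    excess kinetics in a capillary, and chromatogram synthesis/analysis with
    circular dichroism based enantiomeric excess calibration.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
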