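Package: abvisc
Title: Predicting High-Concentration Antibody Viscosity from Dilute Solution Measurements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Physics-based screening of monoclonal antibody candidates for
    high-concentration viscosity. Implements an isodesmic head-to-head
    self-association model feeding a reptation (entanglement) viscosity law,
    calibration of linear maps from dilute-solution readouts (AC-SINS
    nanoparticle diffusion and the DLS interaction parameter kD) to the
    dimerization constant K, prediction of full concentration-viscosity
    curves, and binary developability classification at a 20 cP cutoff with
    the associated outlier and exclusion rules. Includes a synthetic cohort
    generator for end-to-end validation and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
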