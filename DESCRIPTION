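Package: oxychip
Title: Transport Modelling for Oxygen- and Drug-Gradient Microphysiological Chips
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale transport model of a dual-gradient tumour-microenvironment
    chip: steady Darcy flow through a porous hydrogel, transient and steady
    advection-diffusion of dissolved oxygen and drug on a plan-view grid,
    inverse calibration of the hydrogel diffusion coefficient from oxygen-probe
    profiles, conversion of cellular oxygen consumption into an equivalent
    deoxygenated-medium influx boundary condition, physiological oxygen-zone
    classification, IC50 estimation from dose-response tables, and binned
    live/dead viability maps under orthogonal oxygen and drug gradients.
    Includes seeded synthetic-data generators for probe readings, dose-response
    tables and live/dead point clouds with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    yaml,
    jsonlite,
    withr,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
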