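Package: oocenter
Title: Active-Diffusion Centering Simulations and Trajectory Statistics for Oocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-dimensional off-lattice agent-based simulations of
    nucleus and droplet centering in mouse oocytes, in which self-propelled
    actin-positive vesicles with a cortex-to-center gradient of motion
    persistence push large passive objects toward the cell center. Also
    provides the trajectory-statistics toolkit used to analyse such motion:
    mean squared displacement and diffusion-coefficient fits, radial
    kinematics and centering kinetics, cumulative directional-bias tests
    against a bootstrap Brownian null, Peclet numbers, and generators of
    synthetic tracks (Brownian, drifted, persistent, exponentially
    centering) for validation and null construction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
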