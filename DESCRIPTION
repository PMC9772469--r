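Package: gaitplanr
Title: Planned Walking at Arbitrary Gaits in a Neuromechanical Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A three-dimensional neuromechanical model of human walking in
    which high-level kinematic motor plans (swing-leg joint targets, trunk
    propulsion, trunk reference lean, and step timing) are transformed
    through internal inverse models into descending commands that modulate
    spinal reflexes driving Hill-type muscles on a 14 degree-of-freedom
    skeleton. The package simulates the closed sensorimotor loop, optimizes
    gait-specific control parameters with a covariance-matrix-adaptation
    evolution strategy against staged cost functions for target step length
    and cadence, generalizes to unlearned gaits by nearest-neighbor
    interpolation in a basis-point library, and performs real-time gait
    transitions by switching control parameters during walking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    generics
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
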