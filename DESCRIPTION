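Package: cavithresh
Title: Cavitation Thresholds from Coupled Bubble-Cluster Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts acoustic cavitation thresholds in water and in soft
    viscoelastic tissue from the radial dynamics of a bubble cluster. Bubble
    size classes evolve under coupled Keller-Miksis equations with a
    Kelvin-Voigt (viscous plus elastic) stress at the bubble wall and a
    mean-field bubble-bubble radiation coupling set by the number density of
    each size class. Provides five inertial-cavitation criteria (expansion
    ratio, wall speed against the liquid or gas sound speed, adiabatic core
    temperature), amplitude threshold searches, frequency sweeps with
    power-law threshold-frequency fitting, the quasi-static Blake threshold,
    and parameter studies over bubble number, cluster composition, shear
    modulus and viscosity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
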