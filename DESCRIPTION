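Package: radcon
Title: Three-Compartment Radicalization-Contagion Dynamics
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Mean-field and stochastic dynamics of a three-compartment
    contagion model of radicalization in a mixed population of inflexible
    core agents, peaceful sensitive agents and opponent (radicalized)
    sensitive agents. Provides the reduced one-dimensional ODE, its
    closed-form trajectory, equilibrium and linear stability analysis, the
    critical inflexible fraction and minimum core-engagement threshold,
    degree-of-radicalization indices, an exact Gillespie contact-process
    simulator as the finite-population counterpart, phase-diagram
    generation over parameter space, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
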