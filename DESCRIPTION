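Package: rcswitch
Title: Multifunctionality and Metastable Switching in Reservoir Computers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how an echo-state reservoir computer trained
    to reconstruct two coexisting circular orbits (the "seeing double" task)
    loses multifunctionality and develops metastable switching dynamics as
    the spectral radius of its random connectivity matrix is decreased.
    Provides sparse random network generation, fixed-step Runge-Kutta
    integration of the driven (open-loop) and autonomous (closed-loop)
    reservoir ODE, ridge-regression readout training over quadratic state
    features, attractor continuation in the spectral radius with local-maxima
    bifurcation summaries, and switching statistics based on a two-threshold
    non-ideal relay: transition detection, log-binned residence-time
    distributions, and escape times from unstable reconstructed orbits.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
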