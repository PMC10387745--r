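Package: stochgrowth
Title: Exact Stochastic Dynamics of Nonlinear Population Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact, approximate, and simulated solutions for the stochastic
    dynamics of density-limited population growth. Implements the classical
    generalized-logistic family of growth models (exponential, logistic,
    Blumberg, Richards, Gompertz) as continuous-time pure-birth processes,
    solves the master equation exactly through hypoexponential waiting-time
    distributions, spectral decomposition of the transition-rate matrix, and
    uniformization, and provides moment-closure approximations, seeded
    Gillespie simulation, two-strain community dynamics, and fixation
    probabilities under serial-passage (growth-dilution) experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    optparse,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
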