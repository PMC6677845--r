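Package: rqmcleap
Title: Randomised Quasi-Monte Carlo for Tau-Leaping Simulation of
    Chemical Reaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fixed-step tau-leaping and chemical Langevin (Euler-Maruyama)
    simulation of well-mixed chemical reaction networks driven by randomised
    quasi-Monte Carlo input streams. Provides mass-action reaction networks
    with built-in birth-death, reversible isomerisation and Schlogl test
    systems; scrambled Sobol' point sets (linear matrix scramble plus digital
    shift) of a-priori fixed dimension; inverse-transform coupling of uniform
    streams to Poisson and normal increments; pooled RQMC estimators with
    unbiased variance estimation; convergence-rate studies of the root mean
    squared error; and a quadrature testbed of additive and product test
    functions with discontinuity transformations that explains the observed
    convergence-rate transitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
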