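Package: conjdyn
Title: Tumor-Immune Conjugate Dynamics with and without an Explicit
    Conjugate Compartment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic and stochastic analysis of a predator-prey style
    model of effector T cell control of a small tumor, comparing a
    three-compartment formulation with an explicit effector-tumor conjugate
    to its quasi-steady-state two-compartment reduction. Provides analytic
    fixed points with eigenvalue-based stability classification and damping
    rates, numerical ODE integration with a convergence-time metric and
    parameter sweeps, and an exact Gillespie stochastic simulator (compiled
    kernel) with extinction, mutation-escape and censoring stopping rules,
    ensemble summaries of extinction-time distributions and extinction
    probabilities, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
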