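Package: pmxbayes
Title: Bayesian Compartmental PK/PD Modelling over Clinical Event Schedules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Bayesian population pharmacokinetic and
    pharmacokinetic/pharmacodynamic modelling driven by NONMEM-convention
    clinical event schedules. Provides analytic, matrix-exponential, numeric
    (Runge-Kutta) and coupled solvers for one- and two-compartment models with
    first-order absorption, including steady-state dosing; the Friberg-Karlsson
    semimechanistic myelosuppression model; an adaptive Hamiltonian Monte Carlo
    sampler with dual-averaging step-size and diagonal-metric adaptation;
    rank-normalized split R-hat and bulk/tail effective sample size
    diagnostics; posterior predictive checks; and Pareto-smoothed
    importance-sampling leave-one-out model comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    deSolve,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
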