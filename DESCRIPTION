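Package: twostepRL
Title: Model-Based Versus Model-Free Control in the Deterministic Two-Step Task
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and hierarchical Bayesian analysis of the deterministic
    two-step (spaceship/planet) decision task used to study the trade-off
    between model-based and model-free control. Provides the task environment
    with bounded Gaussian random-walk rewards, three generative choice models
    (a last-outcome learner with forgetting, optionally with choice stickiness,
    and two dual-system temporal-difference learners), a synthetic-cohort
    generator with correlated subject parameters and treatment-arm effects,
    joint two-session hierarchical Bayesian estimation of drug effects with an
    adaptive MCMC sampler backed by compiled likelihoods, a hierarchical
    logistic regression of stay behaviour, PSIS-LOO model comparison with
    pseudo-BMA weights, parameter recovery, and posterior predictive checks.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
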