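Package: metaenv
Title: Inference-Based Microbial Growth Strategies in Meta-Changing
    Nutrient Environments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying microbial adaptation to discrete nutrient
    environments whose fluctuation statistics themselves change over time
    ("meta-changing" environments). Provides generators for Markov and
    hidden-regime nutrient environments, a switching-state dynamic Bayesian
    model with collapsed Dirichlet-multinomial inference, an exact
    enumeration oracle and a real-time particle filter for the posterior
    predictive nutrient distribution, growth-policy fitness simulations
    (including bet-hedging policies) with spline-based growth-rate
    estimation and bootstrap confidence intervals, closed-form policy
    analysis for two-nutrient Markov environments, and a mass-action ODE
    model of a molecular nutrient-transition counter circuit.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
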