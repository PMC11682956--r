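Package: astpkpd
Title: Population Pharmacokinetic-Pharmacodynamic Modelling and Trial
    Simulation for Weight-Tiered L-Serine Dosing in Pediatric Autism
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population pharmacokinetic-pharmacodynamic (PK-PD)
    analysis of orally administered L-serine (AST-001) in pediatric autism
    spectrum disorder. Provides closed-form two-compartment pharmacokinetics
    with zero-order absorption and allometric pediatric scaling, an
    effect-compartment model linking exposure to adaptive-behavior composite
    scores with linear drug effect and linear natural progression, nonlinear
    mixed-effects estimation (SAEM and Laplace) with likelihood-ratio
    covariate selection and case bootstrap, goodness-of-fit and
    prediction-corrected visual predictive check diagnostics, a synthetic
    pediatric trial generator emulating a three-arm titration and crossover
    design, and a weight-tiered dose scenario simulator for phase-III dose
    selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
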