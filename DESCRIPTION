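Package: thermogrowth
Title: Thermodynamic Modelling of Temperature-Dependent Population Growth Rates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a thermodynamic model of population growth in which a single
    rate-limiting, enzyme-catalysed reaction with an Arrhenius numerator is
    attenuated by two-state denaturation of the catalysing enzyme at both
    temperature extremes.  Provides the closed-form rate model built on the
    Murphy-Privalov convergence-temperature parameterization of the protein
    unfolding free energy, derived protein-thermodynamic summaries (stability
    temperature, optimal growth temperature, 50%-denaturation bounds,
    non-polar hydrogen index), a hierarchical Bayesian fitting engine with
    adaptive Metropolis block updates and adaptive direction sampling for the
    universal unfolding parameters, model-structure comparison by Bayes
    factors, a synthetic-data generator for recovery experiments, and
    single-strain nonlinear least-squares fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
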