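Package: fluxmedia
Title: Multiobjective Bayesian Design of Growth Media with Genome-Scale
    Metabolic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Designs cost-effective growth media for microbial production
    strains by wrapping flux balance analysis (FBA) of a genome-scale
    metabolic model inside a multiobjective Bayesian optimization loop.
    The outer optimizer tunes the upper bounds of nutrient-import
    (exchange) reactions and searches for Pareto-optimal trade-offs
    between growth rate, production flux, and medium component cost,
    using Gaussian-process surrogates with random-weight augmented
    Chebyshev scalarization and expected-improvement acquisition.
    Includes a parsimonious FBA solver, model readers for SBML Level 3
    (fbc flux bounds) and BiGG-style JSON, synthetic toy metabolic
    models with closed-form optima for testing, Pareto front analysis
    (composition PCA, component distributions, perturbation-based
    sensitivity), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    xml2,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    optparse,
    withr
Config/testthat/edition: 3
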