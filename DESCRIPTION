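Package: estabsim
Title: Individual-Based Simulation and Running-Window Logistic Regression
    Analysis of Colonisation Establishment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the establishment success of small founding
    populations of a semi-aquatic invasive amphibian. Provides a spatially
    explicit, daily-time-step individual-based simulator of colonisation on
    hexagonal-grid landscapes with a tropical wet-dry rainfall regime, a
    Latin-hypercube incursion-scenario engine with a population-growth
    establishment criterion, static and 90-day running-window binomial
    generalised linear models of establishment probability, and a model
    evaluation layer (McFadden's R2, binned residuals, stratified k-fold
    cross-validation, nested-model deviance ANOVA, Tukey HSD). Includes
    synthetic generators for landscapes, rainfall and outcome tables so every
    statistical stage is testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    parallel,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
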