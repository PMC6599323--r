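Package: gakinetics
Title: Unstructured Kinetic Modelling of Ganoderic Acid Batch Fermentation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulate, fit and compare unstructured kinetic models of
    ganoderic acid production in submerged batch cultures of Ganoderma
    lucidum. Biomass follows a logistic growth law, product formation the
    Luedeking-Piret model, and sugar consumption a Luedeking-Piret-like
    equation with a maintenance term. Parameters are estimated by
    multi-start nonlinear least squares with per-response goodness of fit
    (R-squared, F). A seeded synthetic-data generator provides triplicate
    time courses with additive or proportional noise, and a comparison
    module computes fold changes, percent increases, peak growth rates,
    productivities and two-sample t tests between wild-type and transgenic
    strains. A small command-line front end ties the pipeline together.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
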