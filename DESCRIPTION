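Package: cytoage
Title: Age-Dependent Reference Modelling for Whole-Blood Cytokine Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterising the age-dependence of stimulated and
    unstimulated whole-blood cytokine concentrations in children, built
    around left-censored lognormal immunoassay data. Provides censored
    (Tobit) covariate screening on log concentrations, censored nonlinear
    mixed-effects age models estimated by adaptive Gauss-Hermite
    quadrature with AIC-based structural model selection, age-specific
    percentile (reference-range) curves, visual predictive checks, and a
    seeded synthetic-cohort simulator emulating a paediatric study
    population, orchestrated as a reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
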