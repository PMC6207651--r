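Package: edgecndd
Title: Edge Effects, Natural Enemies, and Density-Dependent Seedling
    Recruitment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to analyse how proximity to forest edges and
    experimental exclusion of fungal pathogens and insect herbivores
    alter seedling diversity and conspecific negative density
    dependence (CNDD) during the seed-to-seedling transition.
    Includes a synthetic-data generator that reproduces a nested
    edge-gradient sampling design (seed traps and pesticide-treated
    seedling plots within stations), Hill-number diversity indices
    with mixed-model treatment contrasts, and a hierarchical Bayesian
    negative-binomial power-law model of recruitment with a log-normal
    measurement-error correction for latent seed density, fitted by
    MCMC via JAGS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan,
    lme4,
    emmeans,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
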