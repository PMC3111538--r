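Package: phyloregress
Title: Phylogenetic Signal Tests and Phylogenetic Regression with
    Model Comparison
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for phylogenetic comparative regression analysis of
    species-level trait data: Blomberg's K with the mean-squared-error
    randomization test of phylogenetic signal, generalized least-squares
    regression under star (ordinary least squares), Brownian-motion (PGLS)
    and Ornstein-Uhlenbeck (RegOU, with REML estimation of the
    transformation parameter) residual covariance models, likelihood-based
    model comparison across alternative tree topologies and branch-length
    schemes, phylogenetic ANCOVA for threshold-style group contrasts, and a
    seeded synthetic-data generator that reproduces the trait/tree
    structure these analyses assume so that every stage can be validated by
    simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    nlme,
    optparse,
    picante,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
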