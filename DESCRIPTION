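Package: oaquant
Title: Quantitative Genetics of Larval Tolerance to Ocean Acidification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the evolutionary potential of marine fish
    larvae facing ocean acidification. Implements a crossed-breeding-design
    simulator (factorial sire-by-dam families reared in replicated tank
    blocks under ambient and acidified seawater), pedigree additive
    relationship algebra, a Bayesian multivariate animal model fitted by
    Gibbs sampling with inverse-Wishart priors (partitioning phenotypic
    covariance into additive genetic, maternal, block, and residual
    components across four traits: mortality and growth in each
    environment), posterior summaries (heritabilities, variance
    proportions, cross-environment genetic and maternal correlations,
    highest-posterior-density intervals, Heidelberger-Welch convergence
    diagnostics), single-generation selection-response projections, and a
    small meta-analysis toolkit for acidification-added larval mortality
    across published experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    coda,
    knitr,
    rmarkdown
Config/testthat/edition: 3
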