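Package: cochlevol
Title: Comparative Phylogenetics of Cochlear Morphology, Hearing Limits and
    Echolocation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analyses of inner-ear evolution: basilar
    membrane arc length and cochlear turn counts from 3D landmark paths,
    allometric regression with prediction-interval outlier classification,
    Brownian-motion ancestral state reconstruction (independent contrasts and
    generalized least squares), Pagel's lambda phylogenetic signal with
    likelihood-ratio tests, phylogenetic generalized least squares and a Gibbs
    sampler for Bayesian phylogenetic mixed models with pMCMC and DIC model
    comparison, reversible-jump MCMC detection of branch-specific rate shifts,
    and calibration regressions predicting hearing limits and echolocation
    call frequencies from cochlear morphology. Includes seeded simulators for
    Yule trees, Brownian traits with clade rate multipliers, cochlea-like
    spiral landmark paths, and joint trait/audiogram study datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    nlme,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
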