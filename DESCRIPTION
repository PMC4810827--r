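Package: foodwebERGM
Title: Exponential Random Graph Models for Directed Food Webs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing directed, binary food webs with exponential
    random graph models (ERGMs). Provides ecologically interpreted
    configuration statistics (alternating stars, shared-partner and
    triangle terms with motif readings such as generalist, keystone,
    tri-trophic chain, omnivory, apparent and exploitative competition),
    Metropolis-Hastings simulation of food webs from a fitted model,
    Monte-Carlo maximum-likelihood estimation by Robbins-Monro stochastic
    approximation with convergence t-ratios and standard errors,
    simulation-based goodness of fit over a 32-statistic suite, descriptive
    triad-census motif analysis against random-network null models,
    niche-model synthetic food-web generation, and before/after comparison
    of fitted parameters across an ecological regime shift.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
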