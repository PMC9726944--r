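Package: fossildiv
Title: Bayesian Birth-Death Inference from Fossil Occurrence Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Preservation-aware Bayesian inference of origination and
    extinction dynamics from stage-binned fossil occurrence tables.
    Implements Poisson preservation models (homogeneous, hump-shaped
    non-homogeneous, and time-variable) with optional gamma rate
    heterogeneity, joint MCMC estimation of per-taxon lifespans and
    piecewise origination/extinction rates with either fixed stage-boundary
    shifts or reversible-jump shift detection, Weibull age-dependent
    extinction, covariate-driven (multivariate) birth-death with horseshoe
    shrinkage, multiple-clade diversity dependence between ecological
    guilds, and deterministic post-processing (diversity trajectories,
    extinction severity, fold changes over background, effective sample
    sizes). A forward simulator of clade histories and their fossilisation
    provides ground-truth data for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
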