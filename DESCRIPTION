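Package: litterRRM
Title: Threshold Random Regression Animal Models for Litter Size Across
    Parities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Bayesian analysis of litter size as a categorical trait that
    changes along a ewe's parity trajectory. Provides pedigree algebra
    (Meuwissen-Luo inbreeding and Henderson's sparse inverse numerator
    relationship matrix), normalized Legendre polynomial trajectory bases,
    a Gibbs sampler with liability augmentation for threshold random
    regression and repeatability animal models with heterogeneous
    parity-class residual variances, post-Gibbs summaries (posterior
    means, highest posterior density intervals, exceedance probabilities,
    effective sample size), per-parity genetic parameter trajectories
    (heritability, permanent-environment fraction, genetic and phenotypic
    correlation matrices), and a synthetic-data generator that emulates
    family-rotation sheep breeding schemes for parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
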