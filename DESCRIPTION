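Package: holosim
Title: Hologenome Simulation and Bayesian Variance Partitioning for
    Genome-Microbiome-Phenotype Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven simulation of quantitative phenotypes jointly
    influenced by host genotypes and microbiome composition under six causal
    scenarios (null, genome-only, microbiome-only, indirect, joint, recursive),
    using a correlation-constrained permutation algorithm that links observed
    taxon abundances to simulated genetic values without altering abundance
    marginals. Includes Gibbs samplers for spike-slab (Bayes C) variable
    selection and multi-kernel RKHS/GBLUP regression with Hadamard interaction
    kernels, per-iteration heritability and microbiability partitioning,
    holdout prediction, and an experiment layer for association-study power
    and variance-component bias.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    mclust,
    vcfR,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
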