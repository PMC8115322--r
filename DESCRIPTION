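Package: paleokin
Title: Kinship and Social Structure Inference from Low-Coverage Ancient DNA
Version: 0.2.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reconstructing biological kinship and cemetery social
    structure from low-coverage ancient genomes. Computes genotype likelihoods
    from allele pileups under a sequencing-error and post-mortem-damage model,
    estimates pairwise identity-by-descent coefficients (k0, k1, k2) by
    maximum likelihood, classifies relationship degrees, and cross-checks
    calls with a pseudo-haploid mismatch classifier. Cohort-level statistics
    include haplotype diversity, Hudson's F_ST, a genotype-likelihood-based
    MCMC estimator of the inbreeding coefficient, and molecular sexing from
    X/Y read counts. Bespoke cemetery statistics link genetic kinship to
    burial location (permutation and exact tests for spatial clustering of
    relatives), burial composition (hypergeometric attribute tests), and
    grave-good status concordance among kin dyads. A pedigree gene-dropping
    simulator with a deamination-like error model generates fully synthetic
    cohorts for validation, and a bundled Early Bronze Age cemetery dataset
    (Mokrin) illustrates the workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    vcfR,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
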