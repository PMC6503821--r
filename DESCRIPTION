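Package: invabc
Title: Coalescent ABC Reconstruction of Recent Invasion Histories from SNP Data
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Likelihood-free (approximate Bayesian computation) inference of the
    colonization history of recently established invasive populations from
    reduced-representation SNP genotypes. Reads multi-sample VCF genotype
    matrices with a population map, filters and subsamples them into complete
    matrices, computes a battery of within- and between-population summary
    statistics (segregating sites, private sites, expected heterozygosity,
    Nei's multilocus G_ST, joint-site-frequency-spectrum axis statistics),
    simulates competing colonization scenarios (founding bottlenecks,
    migration, hyperpriors on source effective sizes) under a multi-deme
    coalescent implemented in C++, and performs ABC model selection (rejection,
    neural-network and random-forest classifiers), regression-adjusted
    parameter estimation with highest-density intervals, leave-one-out
    cross-validation on pseudo-observed datasets, and posterior predictive
    checks. Ships a synthetic-data generator emulating study-shaped RAD-seq
    SNP panels with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    nnet,
    ranger,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
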