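Package: cdassoc
Title: Collective SNP-Set Association with Quantitative Traits by
    Continuous Discriminant Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the genotype distribution of a SNP set conditional on a
    continuous phenotype, with phenotype-linear single-SNP and pairwise
    interaction parameters fitted by L2-penalized pseudo-likelihood
    (continuous discriminant analysis). Phenotypes are predicted by Bayes
    inversion of the fitted distribution and association of the whole SNP
    set is scored by the cross-validated prediction correlation R, with
    significance from a Fisher transformation against a permutation-estimated
    null mean. Includes a ridge-regression comparator with all pairwise
    interaction terms, an exact-enumeration model simulator, covariate
    stratified meta-analysis with sample-size-weighted parameter averaging,
    pathway-based SNP-group construction from BED gene spans and GMT gene
    sets, LD pruning, and split-half broad-sense heritability estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    vcfR
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
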