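Package: hsqtl
Title: Phenotype-to-QTL Mapping for Heterogeneous Stock Rodent Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end analysis pipeline for genome-wide association
    mapping of behavioral traits in outbred heterogeneous stock (HS) rodent
    cohorts. Provides a synthetic HS-like cohort simulator with planted
    quantitative trait loci (QTLs), SNP quality control (missingness, minor
    allele frequency, Hardy-Weinberg equilibrium), two-site phenotype
    preparation by covariate screening and rank-based inverse-normal
    transformation, genetic relatedness matrices (full and
    leave-one-chromosome-out), AI-REML estimation of SNP heritability with a
    boundary likelihood-ratio test, mixed-model association scans with
    permutation-derived family-wise significance thresholds, rule-based QTL
    calling with iterative conditional mapping and linkage-disequilibrium
    intervals, colocation against local expression-annotation tables, and
    similarity-network clustering of animals into addiction-severity
    phenotypes via a Bayesian stochastic block model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
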