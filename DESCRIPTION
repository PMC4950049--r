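Package: ibdep
Title: Pedigree and Genomic Inbreeding Estimators and Inbreeding
    Depression Models for Wild Populations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying inbreeding and inbreeding depression in
    free-living populations with overlapping generations. Implements
    pedigree inbreeding coefficients via tabular kinship, genomic
    estimators from SNP data (multilocus homozygosity, the
    allele-frequency-weighted GRM diagonal estimator, and runs of
    homozygosity called by a scanning-window algorithm), identity
    disequilibrium (g2), genotype quality control with an exact
    Hardy-Weinberg test and variance-inflation-factor LD pruning, and
    mixed-model regressions of traits and fitness on individual and
    maternal inbreeding (animal models with pedigree relationship
    matrices, and binomial/Poisson GLMMs). A gene-dropping simulator
    provides pedigrees, linked SNP genotypes and known realized
    autozygosity so every stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    lme4,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
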