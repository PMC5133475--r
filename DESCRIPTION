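Package: famlmm
Title: Kinship-Adjusted Association, Epistasis and Combined-Evidence
    Tests for Family Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Replication analysis toolkit for family-structured genetic
    studies of blood-pressure and expression phenotypes. Implements
    spectrally transformed linear mixed models with a realized
    relationship or centered kinship matrix for single-SNP association,
    nested mixed-model likelihood-ratio tests for additive-by-additive
    SNP-SNP interaction on expression traits, a combined evidence
    statistic (the sum of -log10 p over a candidate set) with a
    Gaussian-copula Monte-Carlo null that accounts for LD-induced
    correlation between nearby tests, Bonferroni and
    Benjamini-Yekutieli multiple-testing utilities, analytic power for
    single-SNP quantitative-trait tests, and a pedigree gene-dropping
    simulator that generates family genotype, longitudinal
    blood-pressure and expression data with known truth for
    calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
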