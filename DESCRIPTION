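Package: fstprior
Title: SNP Prioritization for Genomic Selection Using Phenotype-Stratified FST
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time simulation of livestock populations under
    truncation selection, Nei FST scanning between phenotype-extreme
    subpopulations to prioritize SNPs from high-density marker panels, and
    Gibbs-sampled Bayesian whole-genome regression (a BayesA-style model on
    the preselected SNPs, BayesB, and BayesC) to predict genomic breeding
    values. Includes accuracy and QTL-tagging evaluation against true
    breeding values, readers and writers for PLINK raw dosage tables and
    VCF, and an experiment driver that runs the full
    simulate-score-select-fit-evaluate pipeline over scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    data.table,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
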