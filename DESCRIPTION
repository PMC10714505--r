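Package: frequentmer
Title: Group-Exclusive k-mer Signatures (Frequentmers) for Metagenomic Cohort Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts "frequentmers" from metagenomic sequencing reads: short
    k-mers recurrently present in at least r samples of one cohort (patients or
    healthy controls) and entirely absent from every sample of the other
    cohort. Frequentmers are derived fold-by-fold under stratified
    cross-validation so that feature definitions never leak test information,
    then used as binary presence/absence features for logistic regression and
    gradient-boosted tree classifiers of sample disease status. The package
    also identifies exposure-specific frequentmer subsets, compares per-sample
    frequentmer profiles by Jaccard index, traces high-importance frequentmers
    back to the reads that contain them (emitting FASTA for downstream
    taxonomic classification), and ships a planted-marker synthetic metagenome
    generator that provides ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    glmnet,
    xgboost,
    pROC,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
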