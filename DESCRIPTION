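Package: polycrossGS
Title: Genomic Selection Evaluation for Polycross Recurrent-Selection
    Breeding Programs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate genomic selection in outbreeding forage
    breeding programs built around recurrent polycross selection, as in
    perennial ryegrass (Lolium perenne).  Provides genotype/map/phenotype
    input-output with -1/0/1 additive SNP coding, a forward breeding-program
    simulator (drift burn-in, Poisson/Haldane meiosis, polycross half-sib
    families, sward family-mean phenotypes at controlled heritability),
    half-sib broad-sense heritability estimation by one-way ANOVA with
    leave-one-out jackknife, linkage-disequilibrium decay against a genetic
    map with Sved effective population size and training-population design
    formulas, ridge-regression BLUP (REML via spectral decomposition)
    implemented from first principles, k-nearest-neighbour regression with
    cross-validated k, random-forest and gradient-boosting adapters, and an
    evaluation pipeline scoring Spearman prediction accuracy across
    differently composed training populations.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    Rcpp,
    randomForest,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
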