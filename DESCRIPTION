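Package: riverpopgen
Title: Riverscape Population Genetics of Fragmented Dendritic Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for assessing the effect of migration barriers
    (dams with and without fishpasses, natural falls) on the genetic structure
    of fish populations sampled along a dendritic river network. Reads diploid
    microsatellite genotypes (GENEPOP), computes per-site diversity (observed
    and unbiased expected heterozygosity, Weir-Cockerham F_IS with permutation
    tests, rarefied allelic richness), pairwise and global Weir-Cockerham
    F_ST with locus bootstraps, linkage-disequilibrium effective population
    size with jackknife confidence intervals, Mantel and partial Mantel tests,
    AIC selection among candidate barrier regressions with permutation
    p-values and commonality analysis, virtual-distance conversion of barrier
    effects, and least-squares stream-tree mapping of genetic distance onto
    river sections. Includes a forward-time stepping-stone simulator of
    microsatellite evolution on barrier-annotated river networks so every
    stage is testable on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    pracma,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
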