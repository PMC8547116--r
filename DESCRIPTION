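Package: landgen
Title: Landscape Genetics of Linearly Distributed Plant Populations
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-genetic analysis of codominant microsatellite
    data sampled along linear coastal landscapes: per-population diversity
    statistics (observed and unbiased expected heterozygosity, rarefied
    allelic richness, private alleles, Garza-Williamson M, bootstrap FIS),
    exact and Monte-Carlo Hardy-Weinberg tests, linkage-disequilibrium
    permutation tests, pairwise Weir-Cockerham FST, least-cost resistance
    distances over raster landscapes, anisotropic wind-connectivity cost
    matrices, climatic dissimilarity, Mantel and multiple-matrix-regression
    (MMRR) permutation inference, DAPC and spatial PCA for exploratory
    structure, and a forward-time drift-migration simulator that generates
    genotypes, landscapes, wind fields and climate surfaces under known
    scenarios so that every stage of the pipeline can be validated against
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    geosphere,
    MASS,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    vegan,
    optparse
Config/testthat/edition: 3
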