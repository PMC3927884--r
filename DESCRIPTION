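Package: stockpriority
Title: Genetic Stock Delineation and Conservation Prioritization for
    Anadromous River Herring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for delineating genetic stocks of anadromous fishes
    from multilocus microsatellite genotypes and for prioritizing both
    monitored and unmonitored spawning populations for conservation.
    Implements GENEPOP input/output, per-river diversity statistics
    (observed and unbiased expected heterozygosity, Weir-Cockerham FIS,
    rarefied allelic richness), Hardy-Weinberg and linkage-disequilibrium
    permutation tests with sequential Bonferroni correction, lnRV/lnRH
    neutrality screens, Weir-Cockerham theta and Hedrick standardized
    F'ST, genic heterogeneity tests with Fisher combination, hierarchical
    AMOVA, Nei's DA distance, POWSIM-style power assessment, an admixture
    Gibbs sampler with Evanno delta-K model choice, marine least-cost
    distances with Mantel tests of isolation by distance, Theil-Sen and
    Mann-Kendall trend analysis of demographic time series, and
    threshold-based conservation prioritization rules that extend stock
    designations to demographically unmonitored rivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    igraph,
    geosphere,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
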