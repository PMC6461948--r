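Package: halfsibsim
Title: Stochastic Simulation of Half-Sib Family Recurrent Selection in
    Cross-Pollinated Crops
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gene-to-phenotype stochastic simulation of recurrent selection
    programs for open-pollinated (cross-pollinated) species such as forage
    grasses. Builds a genotype-environment system from a linkage map and
    additive/dominance QTL effects, simulates meiosis with map-based
    recombination (Haldane mapping function), creates half-sib families by
    polycross with selfing excluded, calibrates trial error variance to a
    target half-sib family-mean heritability, and runs among-family (AHS)
    and among-and-within-family (AWHS) selection strategies over many
    cycles. Reports genetic gain, 90% cumulative gain (dG90) and the cycles
    needed to reach it, Hamming distance to the ideal genotype, and allele
    fixation rates, with a factorial scenario runner for strategy
    comparison studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
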