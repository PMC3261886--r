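Package: coaldelta
Title: Deep Coalescence and Multilocus Species-Tree Inference for Shallow
    Mammalian Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference toolkit for studying how deep
    coalescence (incomplete lineage sorting) distorts divergence-time
    estimates obtained from gene trees, and how multilocus Bayesian
    species-tree methods recover true split times and topologies from
    mixtures of mitochondrial and nuclear markers.  Includes a
    multispecies-coalescent genealogy simulator, an HKY85+Gamma sequence
    simulator, a distance-based gene-tree estimation pipeline with
    Langley-Fitch clock fitting and K-score rescaling, a Bayesian MCMC
    sampler for species-tree divergence times and population sizes (with
    optional topology sampling for five-taxon radiations), and the
    discordance statistics and condition grids of the underlying
    simulation study.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
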