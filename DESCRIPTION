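Package: npdiversity
Title: Similarity-Network Analysis of Natural-Product Chemical Diversity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fingerprint-based similarity-network analysis of natural-product
    compound collections. Computes hashed circular (Morgan, radius 2)
    fingerprints from SMILES, builds Dice-similarity networks at a
    configurable cutoff, partitions them into clusters by connected
    components, and derives the statistics used to characterise microbial
    natural-product chemical space: cluster sizes, median within-cluster
    degree, taxonomic purity, rank-similarity profiles, year-stratified
    singleton (novelty) rates, a macrocyclic-lactone ring census, and the
    combinatorial capacity of idealized polyketide assembly lines. Includes
    a synthetic compound-family generator with known ground truth so the
    full pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    xml2
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
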