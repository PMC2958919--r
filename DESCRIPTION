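Package: aflpdelim
Title: Species Delimitation and Introgression Inference from Dominant
    Multilocus Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multilocus analysis pipeline for delimiting species and
    discriminating incomplete lineage sorting from introgression in
    closely related species sampled with dominant markers (AFLP).
    Provides missing-data-aware Jaccard distances, neighbor-joining with
    marker bootstrap, neighbor-net split networks, non-metric
    multidimensional scaling with Gaussian mixture model selection
    (optionally with a uniform noise component), Bayesian population
    assignment for dominant phenotypes with and without admixture,
    Evanno's delta-K statistic, Dirichlet-process clustering with a
    mean-partition summary, gene-tree/species concordance scoring with
    coalescence-depth profiling, alignment base-composition
    heterogeneity tests (chi-square and matched-pairs tests of
    symmetry, RY recoding), and a synthetic-data module so every stage
    is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    phangorn,
    pracma,
    mclust,
    igraph,
    Biostrings,
    geosphere
Suggests:
    testthat (>= 3.0.0),
    vegan,
    MASS,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
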