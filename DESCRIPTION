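Package: regpatterns
Title: Dual-Profile Regulatory Pattern Classification for Single-Cell
    Cluster Pairs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies pairs of single-cell clusters as matched, convergent
    or divergent by contrasting the similarity structure of their
    transcription-factor expression profiles with that of their effector-gene
    profiles. Provides correlation-based profile distances, Ward dendrograms
    with sister-cluster (cherry) extraction and multiscale-bootstrap clade
    support, population-level rank-based similarity calls, gene-subsampling
    robustness checks, tree-to-tree discordance metrics, differential
    RNA-binding-protein marker analysis between paired clusters,
    non-negative least squares cluster mapping, Jaccard-index cluster
    stability, binary combinatorial marking matrices, and a negative-binomial
    synthetic-data generator with planted cluster pairs for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    jsonlite,
    ape,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
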