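Package: schicgraph
Title: Hypergraph Representation Learning for Single-Cell Hi-C Embedding and Imputation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Represents a single-cell Hi-C dataset as a hypergraph in which each
    hyperedge joins one cell node and two genomic-bin nodes, and trains a
    hyperedge-prediction neural network (static/dynamic embeddings with
    self-attention and an optional cell-dependent graph neural network) to embed
    cells and impute sparse intra-chromosomal contact maps. Supports
    classification, ranking and zero-inflated negative-binomial training
    objectives, embedding-space neighbor smoothing with batch-balanced neighbor
    selection, batch-effect neutralization during imputation, and downstream
    single-cell A/B-compartment scores, insulation profiles and TAD-like
    boundary variability statistics. Ships a synthetic single-cell Hi-C
    simulator with planted cell types, compartments, domains, batches and
    co-assayed 1D signals so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    mclust,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
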