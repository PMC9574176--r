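Package: cellbridge
Title: Online Integration of Multi-Batch Single-Cell Data in a Common
    Cell-Embedding Space
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Integrates heterogeneous single-cell datasets (scRNA-seq,
    scATAC-seq, and precomputed cross-modality gene-activity matrices) by
    training a variational autoencoder whose encoder never sees batch
    labels and whose single-layer decoder applies domain-specific batch
    normalization, so that cells from any batch are projected into a
    common, batch-invariant low-dimensional embedding. New batches are
    integrated online by pushing them through the frozen encoder, without
    retraining. Ships the matching preprocessing recipes (per-batch 0-1
    max-abs scaling over selected variable features), k-nearest-neighbour
    label transfer, Leiden clustering and UMAP of the latent space, a full
    integration-quality metric suite (ARI, NMI, silhouette, batch entropy
    mixing, iLISI/cLISI, over-correction score, macro F1), and a seeded
    synthetic multi-batch data generator with partial-overlap designs for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    uwot,
    RANN,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    cluster,
    rhdf5,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
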