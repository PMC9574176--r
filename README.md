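# cellbridge

Online integration of multi-batch single-cell data in a common
cell-embedding space.

## The problem

Single-cell experiments (scRNA-seq, scATAC-seq) measured across donors,
protocols, or laboratories carry strong non-biological *batch effects*
that dominate naive analyses: unintegrated data clusters by batch, not by
cell type. Classical integration tools remove batch effects by searching
for cell correspondences across the batches at hand, which (i) tends to
*over-correct* partially overlapping datasets — erroneously merging cell
types that exist in only some batches — and (ii) must be re-run from
scratch every time a new batch arrives, perturbing all previous results.

`cellbridge` is for analysts who need a *reference* embedding that new
data can join without retraining: build an integrated cell space once,
then project each arriving batch through a frozen projection function
("online" integration), annotate the new cells by label transfer from the
reference, and quantify the result with a full metric suite.

## The model

A variational autoencoder with an asymmetric treatment of batch:

- **batch-free encoder** `x → (μ, log σ²)`: fully connected
  `features → 1024` — BatchNorm — ReLU — two linear heads `1024 → 10`.
  Batch labels never enter, so the 10-dimensional latent posterior mean μ
  carries only batch-invariant structure; the frozen encoder is the
  projection function used for online integration.
- **batch-conditioned decoder** `z → x̂`: a single linear layer
  `10 → features`, then *domain-specific batch normalization* (DSBN — one
  BatchNorm branch per training batch, switched by the cell's batch
  label), then a sigmoid. Batch-specific variation is reinstated only at
  reconstruction.
- **objective**: `BCE(x, x̂) + β·KL(N(μ,σ²) ‖ N(0,I))` with β = 0.5
  (BCE summed over features, both terms averaged over cells), optimized by
  Adam (lr 2e-4, weight decay 5e-4, betas 0.9/0.999) on mini-batches of 64
  cells drawn from *all* batches pooled, with early stopping (patience 10
  epochs, cap 30,000 steps).

Inputs are counts preprocessed to `[0, 1]`: filter (≥600 genes/cell,
≥3 cells/gene), total-normalize to 10,000, `log1p`, top 2,000 highly
variable genes, per-batch max-abs scaling (scATAC-seq: binarize, top
30,000 variable peaks, median total-normalization). The metric suite
implements ARI, NMI, silhouette (on UMAP), batch entropy mixing
(probe-neighbourhood entropy with a global-proportion correction),
iLISI/cLISI (Gaussian-kernel perplexity 30), an over-correction score
(fraction of k-NN with inconsistent cell types), macro F1, confusion and
centroid-similarity matrices.

## Worked example

Simulate three batches sharing four cell types under a strong batch
effect, integrate, hold one batch out, and annotate it by projection +
label transfer:

```r
library(cellbridge)

sce <- simulateMultibatch(simSpec(seed = 1))   # 3 batches x 4 types x 75
sc  <- preprocessRNA(sce, params = preprocessParams("rna",
         minGenesPerCell = 50, nTopFeatures = 2000))

fit <- fitModel(sc,
         modelConfig(ncol(scaledValues(sc)), nDomains = 3, hiddenDim = 256),
         trainConfig(seed = 1, maxIterations = 2500))

emb <- referenceEmbedding(fit, sc)
cl  <- clusterLatent(emb, seed = 1)            # Leiden, resolution 0.5
um  <- umapEmbed(emb, seed = 1)

adjustedRandIndex(cellTypeLabels(sc), cl)
batchEntropyMixing(um, batchLabels(sc),
                   cellType = cellTypeLabels(sc), seed = 1)$rescaled
overCorrectionScore(latentCoords(emb), cellTypeLabels(sc))
```

```
[1] 1
[1] 0.9393402
[1] 3.703704e-05
```

The latent clusters recover the planted cell types essentially perfectly
(ARI ≈ 1; on the raw, unintegrated PCA embedding the same pipeline yields
ARI ≈ 0.43 because cells cluster by batch), batches are well mixed
within shared types (rescaled batch entropy near 1), and almost no cell
sits among neighbours of a different type (over-correction near 0).
Projecting new data needs no retraining:

```r
hold <- sce[, sce$batch == "batch3"]           # pretend this just arrived
al   <- alignProjectionFeatures(
          SummarizedExperiment::assay(hold, "counts"), featureIds(fit),
          batch = droplevels(hold$batch),
          params = preprocessParams("rna", minGenesPerCell = 50))
qry  <- projectCells(fit, al)                  # frozen encoder, read-only
lab  <- transferLabels(referenceEmbedding(fit, sc), qry, k = 30)
mean(as.character(lab$predicted) == as.character(hold$cell_type))
```

```
[1] 1
```

A thin command-line wrapper over the same functions ships in
`inst/scripts/cellbridge.R` (`simulate`, `preprocess`, `train`, `project`,
`annotate`, `evaluate` subcommands).

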