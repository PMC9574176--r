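---
title: "cellbridge: model, metrics, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{cellbridge: model, metrics, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The integration model

`cellbridge` integrates multi-batch single-cell data by learning a single
projection function that maps every cell -- from any batch, including
batches that arrive after training -- into a common low-dimensional
embedding in which batch effects are absent but cell-type structure is
preserved. The model is a variational autoencoder with a deliberate
asymmetry:

* **The encoder never sees batch labels.** It is a two-layer network
  (`features -> 1024`, batch normalization, ReLU, then two linear heads
  `1024 -> 10` for the posterior mean $\mu$ and log-variance
  $\log\sigma^2$). Because nothing batch-specific enters, everything
  batch-specific must be explained elsewhere, and the encoder is forced to
  encode only the shared biology. This is the property that makes *online*
  integration possible: a new batch is integrated by simply evaluating the
  frozen encoder, with no retraining and no modification of existing
  coordinates.
* **The decoder owns the batch effects.** It is a single linear layer
  `10 -> features` followed by *domain-specific batch normalization*
  (DSBN) and a sigmoid. DSBN keeps one set of batch-norm affine parameters
  and running statistics per training batch (domain) and routes each cell
  through its own domain's branch. Batch-specific distortion is thus
  reinstated only at reconstruction time.

Sampling uses the standard reparameterization
$z = \mu + \sigma \odot \varepsilon$, $\varepsilon \sim N(0, I)$. The
objective is

$$\mathcal{L} = \mathrm{BCE}(x, \hat x) + \beta\, D_{KL}\!\left(N(\mu,
\sigma^2)\,\|\,N(0, I)\right), \qquad \beta = 0.5,$$

with the binary cross entropy summed over features and averaged over
cells, and the KL term likewise averaged over cells. The down-weighted KL
($\beta = 0.5$ rather than 1) relaxes the pull toward the prior enough for
batches to align flexibly in the latent space.

Training uses Adam (learning rate 2e-4, weight decay 5e-4, moment decay
0.9/0.999) on mini-batches of 64 cells drawn from a seeded random
permutation of **all** cells pooled across batches -- never from a single
batch. Pooled mini-batches follow the overall mixture distribution, and
the encoder's batch-norm layer aligns each mini-batch's deviation to that
global distribution; this is one of the three design elements (batch-free
encoder, DSBN decoder, all-batch sampling) whose removal the ablation
variants quantify. Training stops at 30,000 steps or when the epoch-mean
total loss has not improved by more than `tol` (default 1e-4) for 10
consecutive epochs; the best-epoch parameters are kept.

The latent representation exported everywhere downstream is the posterior
mean $\mu$, not a sample: projection must be a deterministic, reproducible
map.

## Ablation variants

`modelConfig(variant = ...)` exposes the test-variants used to attribute
performance to each design element: `encoder_with_batch` (one-hot batch
block appended to the encoder input; breaks online use), `no_dsbn` (shared
batch norm in the decoder), `sample_by_batch_no_bn` (single-batch
mini-batches and no encoder batch norm), and `plain_autoencoder` (no
sampling, no KL). The package's acceptance suite checks the expected
direction: the plain autoencoder and by-batch-sampling variants integrate
worse than the full model on over-correction or batch mixing.

# Preprocessing recipes

**scRNA-seq** (`preprocessRNA`): drop cells with fewer than 600 expressed
genes and genes present in fewer than 3 cells; normalize each cell's total
to 10,000; `log1p`; keep the 2,000 most highly variable genes; scale each
gene to [0, 1] within each batch by its per-batch maximum (max-abs
scaling). The sigmoid output of the decoder matches this [0, 1] range, and
per-batch scaling removes gross scale differences before the model ever
sees the data.

**scATAC-seq** (`preprocessATAC`): binarize; drop features in fewer than 3
cells; keep the 30,000 most variable peaks/bins; normalize each cell's
total to the median total; per-batch max-abs scaling. Binarization
precedes the feature filter, matching the order in which the recipe is
stated. Cross-modality data enter as a precomputed gene-activity matrix
treated as one more "batch" of the RNA recipe; computing gene activities
is out of scope.

Two details are deliberate choices where the recipes are underspecified:

* **Variable-gene selection** is dispersion-based per batch (variance/mean
  of the de-logged values, z-scored within 20 mean-quantile bins), and
  genes are ranked by the number of batches in which they are highly
  variable, with ties broken by mean normalized dispersion. A batch-aware
  rule avoids selecting genes whose variability is purely batch-driven.
* **ATAC variability** is the per-feature variance of the binarized
  matrix -- the simplest statistic consistent with "most variable"; it is
  recorded in the provenance so it can be swapped.

**Projection-time alignment** (`alignProjectionFeatures`): a new batch is
normalized by its own modality recipe, restricted and re-ordered to the
trained model's feature vocabulary (missing features zero-filled), and
max-abs scaled *within the new batch only*. Scaling is defined per batch
and projection treats arriving data as a new batch; reusing the reference
batch maxima would leak reference composition into the query. A
consequence worth knowing: re-supplying a training batch reproduces its
training values exactly only when the training gene filter removed nothing
(the projection side cannot reconstruct which low-prevalence genes
training dropped before computing cell totals).

# Projection, label transfer, clustering

`projectCells` evaluates the frozen encoder in eval mode (batch norm uses
running statistics), so each cell's coordinates are a pure function of its
own profile: duplicated cells get identical coordinates, co-batched cells
do not interact, and the model file is bit-for-bit unchanged. Unseen
batches need no domain registration because the decoder is never touched.

`transferLabels` is k-nearest-neighbour majority voting in the latent
space (Euclidean, `k = 30` by default -- the package's other neighbourhood
sizes are also 30, and the classifier is insensitive to k in that range).
Ties go to the tied label with the smallest summed neighbour distance,
then lexicographically. When query and reference are the same set, each
cell's self-match is excluded (except in the documented identity test).

`clusterLatent` runs Leiden (modularity objective, resolution 0.5) on the
Jaccard-weighted shared-nearest-neighbour graph of the 30-NN latent graph,
the construction the field's standard toolkits use; `umapEmbed` uses
`n_neighbors = 30`, `min_dist = 0.1`, Euclidean. Both are seeded and
deterministic. Joint views of reference plus projected cells recompute
UMAP on the concatenated latent coordinates -- the latent space, not any
particular UMAP, is the invariant object.

# The metric suite

Conventions: natural logarithms, $0 \log 0 = 0$, Euclidean distances.
Clustering-based scores (ARI, NMI) and the over-correction score are
computed on the latent coordinates; silhouette, batch-entropy mixing and
LISI take the 2-D UMAP as input.

* **ARI / NMI** -- chance-adjusted pair agreement and normalized mutual
  information between Leiden clusters and the true types. A constant
  partition has zero entropy; NMI is defined as 0 there, with a warning.
* **Silhouette** -- mean of $(b - a)/\max(a, b)$ over cells on the UMAP;
  singleton types score 0.
* **Batch entropy mixing** -- around 30 random probe cells per iteration
  (10 iterations), the batch composition $p$ of each probe's 30-NN is
  corrected by the global proportions $P$:
  $p'_i = (p_i / P_i) / \sum_j (p_j / P_j)$, and
  $E = \sum_i p'_i \log p'_i$ is averaged over probes and iterations. The
  printed raw quantity *decreases* with better mixing (it is $\le 0$),
  while the score is described as "high = well mixed"; the package
  therefore reports both the raw value and the headline
  `rescaled` $= -E / \log(\text{batches}) \in [0, 1]$. When cell-type
  labels are available, only types common to all batches are scored, so
  correctly separated batch-specific populations are not punished. Probes
  are drawn without replacement within an iteration, independently across
  iterations.
* **iLISI / cLISI** -- per cell, Gaussian-kernel neighbourhood
  probabilities calibrated by bisection to perplexity 30 over the 90
  nearest neighbours, then the inverse Simpson index of the batch (iLISI)
  or type (cLISI) distribution. Values lie in [1, #categories]. Duplicate
  coordinates fall back to a uniform kernel (bandwidth floor).
* **Over-correction score** -- $1 - \frac{1}{nk} \sum_i \sum_{j \in
  \mathrm{kNN}(i)} I(\text{type}_i = \text{type}_j)$ with $k = 30$ and
  self excluded: the average fraction of neighbours with a *different*
  type. It is a negative index -- higher means distinct types were mixed.
  On its own it rewards under-integration (a completely unmixed embedding
  scores 0), which is why it is always read together with the batch-mixing
  scores.
* **Macro F1** -- unweighted mean of per-class F1 over the union of
  observed classes, for label-transfer evaluation, alongside row-percent
  confusion matrices and centroid-correlation similarity matrices.

# The synthetic data generator

`simulateMultibatch` draws multi-batch counts with known ground truth:
cell types share a baseline expression program and differ in disjoint
marker blocks; batches apply a per-gene multiplicative log-normal
distortion plus a library-size shift; counts are negative-binomial with
extra low-mean dropout (or Bernoulli accessibility profiles in ATAC mode).
The defaults are fixed study conditions, not tuning knobs: ~2,000 counts
per cell, each type marked by a disjoint 12% of the feature space at
8-fold elevation (distinct major cell types differ broadly -- hundreds of
genes at full scale -- not in a handful of markers), batch distortion sd
0.8 (strong enough that unintegrated data clusters by batch, as real
multi-protocol data does), dispersion 0.3, moderate dropout.
`makePartialOverlap` then builds the partial-overlap designs: two batches
keep random subsets of 3-6 of six types, rejection-sampled so the union
covers all six; the intersection size (0-6) is the overlap level.

What the generator does *not* emulate: continuous differentiation
trajectories, nested subtype hierarchies, ambient RNA, doublets, or
batch-by-type interaction effects. Passing the end-to-end checks therefore
demonstrates that the machinery recovers planted discrete structure under
realistic noise -- not that any particular real dataset will integrate
equally well.

# Numerical choices and problem sizes

* Variance head parameterized as log-variance, clamped to [-15, 15];
  sigmoid outputs clamped by 1e-8 inside the BCE logs; batch-norm
  `eps = 1e-5`, running-statistics momentum 0.1 (biased batch variance is
  used both for normalization and for the running update).
* Weights: Kaiming-uniform fan-in initialization (gain $\sqrt 2$ before
  ReLU, 1 elsewhere), zero biases, batch-norm affines at $\gamma = 1$,
  $\beta = 0$; all seeded. Identical seeds give bitwise-identical runs on
  one platform.
* Early stopping monitors the epoch-mean *training* loss -- no validation
  split is prescribed, integration is transductive over the training
  batches, and the monitored quantity only gates when to stop.
* A train-mode mini-batch of one cell is permitted (its batch variance
  degenerates to `eps`) and flagged with a warning.
* The test and acceptance fixtures run the full pipeline at reduced size
  -- 300 genes, 75-100 cells per type and batch, 256 hidden units, 2,500
  optimizer steps -- chosen so that a complete train-and-evaluate cycle
  takes well under a minute while leaving all structure (strong batch
  effects, partial overlap, hold-out projection) intact. The architecture
  audit still checks the full published topology (1024 hidden units, 10
  latent dimensions).

# Known limitations

* The likelihood is Bernoulli/BCE on [0, 1]-scaled values; count
  likelihoods (negative binomial, ZINB) are out of scope.
* DSBN capacity is one affine per batch and feature: a batch whose effect
  is strongly cell-type-dependent is only partially absorbed.
* The `encoder_with_batch` variant exists for ablation only and cannot
  project new data.
* Projection assumes the new batch shares a usable fraction of the
  reference vocabulary; alignment fails loudly at zero overlap and
  zero-fills missing features, which degrades gracefully only while the
  missing fraction stays modest.
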