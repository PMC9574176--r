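# Integration-quality metric suite. Conventions used throughout:
# natural logarithms, 0 * log 0 := 0, Euclidean distances.

#' Adjusted Rand Index between two partitions
#'
#' Chance-adjusted pair-counting agreement computed from the contingency
#' table: 1 for identical partitions, ~0 for random ones. Symmetric and
#' invariant to label renaming.
#'
#' @param a,b equal-length label vectors.
#' @return a number <= 1.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  ai <- sum(choose(rowSums(tab), 2))
  bj <- sum(choose(colSums(tab), 2))
  expected <- ai * bj / choose(n, 2)
  maxIdx <- (ai + bj) / 2
  if (maxIdx == expected) return(1)   # both partitions degenerate/identical
  (sij - expected) / (maxIdx - expected)
}

.entropy <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }

#' Normalized mutual information between two partitions
#'
#' Mutual information divided by the geometric mean of the two label
#' entropies (natural logs): 1 for identical partitions, 0 for independent
#' ones. If either partition is constant (zero entropy) the score is
#' defined as 0, with a warning.
#'
#' @param a,b equal-length label vectors.
#' @return number in \[0, 1\].
#' @export
normalizedMutualInfo <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors must have equal length")
  n <- length(a)
  tab <- table(a, b) / n
  pa <- rowSums(tab)
  pb <- colSums(tab)
  ha <- .entropy(pa)
  hb <- .entropy(pb)
  if (ha == 0 || hb == 0) {
    warning("constant partition: NMI defined as 0")
    return(0)
  }
  mi <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] * log(tab[i, j] / (pa[i] * pb[j]))
  mi <- max(mi, 0)
  min(mi / sqrt(ha * hb), 1)
}

#' Silhouette score of cell types on a 2-D embedding
#'
#' Mean over cells of `(b - a) / max(a, b)` where `a` is a cell's average
#' distance to its own type and `b` its average distance to the nearest
#' other type, computed on the 2-D UMAP coordinates. Cells in singleton
#' types score 0 (with a warning). Degenerate 0/0 cases score 0.
#'
#' @param coords cells x 2 (or more) coordinate matrix.
#' @param labels per-cell type labels.
#' @return number in \[-1, 1\].
#' @export
silhouetteOnEmbedding <- function(coords, labels) {
  coords <- as.matrix(coords)
  labels <- factor(labels)
  if (nlevels(labels) < 2)
    stop("silhouette needs at least 2 cell types")
  n <- nrow(coords)
  D <- as.matrix(dist(coords))
  sizes <- table(labels)
  if (any(sizes == 1))
    warning("singleton cell type(s); their cells score 0")
  s <- numeric(n)
  for (i in seq_len(n)) {
    li <- labels[i]
    if (sizes[li] == 1) { s[i] <- 0; next }
    a <- sum(D[i, labels == li]) / (sizes[li] - 1)
    b <- min(vapply(setdiff(levels(labels), as.character(li)),
                    function(l) mean(D[i, labels == l]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' Batch entropy mixing score
#'
#' Measures local batch mixing around randomly sampled probe cells. Per
#' iteration, `nProbes` cells are drawn (without replacement); for each,
#' the batch composition `p` of its `nNeighbors` nearest neighbours is
#' corrected for the global batch proportions `P`
#' (`p' = (p/P) / sum(p/P)`) and its entropy `E = sum p' log p'` recorded;
#' the score is the average over probes and `nIterations` seeded
#' iterations. The raw score follows the printed formula and is <= 0 (more
#' negative = better mixed); `rescaled = -raw / log(nBatches)` maps it to
#' \[0, 1\] with high = well mixed, which is the headline number.
#'
#' When cell-type labels are supplied (or `mask` given), the score is
#' computed only over cells of types common to all batches, to avoid
#' penalizing correctly separated batch-specific types.
#'
#' @param coords embedding coordinates (cells x dims), typically UMAP.
#' @param batch per-cell batch labels.
#' @param cellType optional per-cell type labels used to build the
#'   common-type mask.
#' @param mask optional logical vector selecting the cells to score.
#' @param nProbes probe cells per iteration (default 30).
#' @param nNeighbors neighbourhood size (default 30).
#' @param nIterations number of probe draws (default 10).
#' @param seed integer seed.
#' @return list: `raw` (<= 0) and `rescaled` (in \[0, 1\]).
#' @export
batchEntropyMixing <- function(coords, batch, cellType = NULL, mask = NULL,
                               nProbes = 30L, nNeighbors = 30L,
                               nIterations = 10L, seed = 0L) {
  coords <- as.matrix(coords)
  batch <- factor(batch)
  if (is.null(mask)) {
    mask <- rep(TRUE, nrow(coords))
    if (!is.null(cellType)) {
      ct <- factor(cellType)
      present <- table(ct, batch) > 0
      common <- rownames(present)[rowSums(present) == nlevels(batch)]
      if (!length(common))
        stop("no cell type is common to all batches; cannot score mixing")
      mask <- ct %in% common
    }
  }
  X <- coords[mask, , drop = FALSE]
  B <- droplevels(batch[mask])
  if (nlevels(B) < 2)
    stop("fewer than 2 batches among scored cells (surviving: ",
         paste(levels(B), collapse = ", "), ")")
  n <- nrow(X)
  if (nNeighbors >= n)
    stop("nNeighbors must be smaller than the number of scored cells")
  P <- as.numeric(table(B)) / n
  set.seed(seed)
  es <- numeric(0)
  for (it in seq_len(nIterations)) {
    probes <- sample.int(n, min(nProbes, n))
    nn <- RANN::nn2(X, X[probes, , drop = FALSE], k = nNeighbors + 1L)
    idx <- nn$nn.idx[, -1, drop = FALSE]
    for (r in seq_along(probes)) {
      p <- as.numeric(table(B[idx[r, ]])) / nNeighbors
      pc <- (p / P)
      pc <- pc / sum(pc)
      es <- c(es, sum(ifelse(pc > 0, pc * log(pc), 0)))
    }
  }
  raw <- mean(es)
  list(raw = raw, rescaled = max(0, min(1, -raw / log(nlevels(B)))))
}

#' Local inverse Simpson's index (iLISI / cLISI)
#'
#' For each cell, neighbourhood probabilities over its nearest neighbours
#' are computed with a Gaussian kernel whose bandwidth is calibrated by
#' bisection so the neighbourhood entropy matches a fixed perplexity
#' (default 30); the per-cell LISI is the inverse Simpson index
#' `1 / sum_y P(y|x)^2` of the label distribution in that soft
#' neighbourhood. With batch labels this is iLISI (effective number of
#' batches mixed around a cell); with type labels, cLISI. Values lie in
#' \[1, number of categories\].
#'
#' @param coords embedding coordinates (cells x dims), typically UMAP.
#' @param labels per-cell labels (batch for iLISI, type for cLISI).
#' @param perplexity Gaussian-kernel perplexity (default 30).
#' @return list: `perCell` numeric vector and `mean`.
#' @export
lisiScore <- function(coords, labels, perplexity = 30) {
  coords <- as.matrix(coords)
  labels <- factor(labels)
  n <- nrow(coords)
  if (nlevels(labels) == 1)
    return(list(perCell = rep(1, n), mean = 1))
  k <- min(n - 1L, max(15L, as.integer(3 * perplexity)))
  perp <- min(perplexity, k - 1)
  nn <- RANN::nn2(coords, coords, k = k + 1L)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  d2 <- nn$nn.dists[, -1, drop = FALSE]^2
  target <- log(perp)
  perCell <- numeric(n)
  for (i in seq_len(n)) {
    di <- d2[i, ]
    # bisection on precision beta so that entropy(p) = log(perplexity)
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:60) {
      w <- exp(-beta * di)
      sw <- sum(w)
      if (sw < 1e-300) { h <- 0; p <- rep(0, length(di)) }
      else {
        p <- w / sw
        h <- -sum(ifelse(p > 0, p * log(p), 0))
      }
      if (abs(h - target) < 1e-7) break
      if (h > target) { lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2
      } else { hi <- beta; beta <- (lo + beta) / 2 }
    }
    if (sum(w) < 1e-300) {               # bandwidth floor: uniform fallback
      p <- rep(1 / length(di), length(di))
    }
    py <- tapply(p, labels[idx[i, ]], sum)
    py[is.na(py)] <- 0
    perCell[i] <- 1 / sum(py^2)
  }
  list(perCell = perCell, mean = mean(perCell))
}

#' Over-correction score
#'
#' One minus the average fraction of each cell's `k` nearest neighbours
#' (self excluded) that share its cell type. 0 means every neighbourhood is
#' type-pure (no erroneous mixing); 1 means no neighbour ever matches. It
#' is a negative index: higher = more severe mixing of genuinely distinct
#' types (over-correction).
#'
#' @param coords embedding coordinates (cells x dims).
#' @param labels per-cell type labels.
#' @param k neighbourhood size (default 30).
#' @return number in \[0, 1\].
#' @export
overCorrectionScore <- function(coords, labels, k = 30L) {
  coords <- as.matrix(coords)
  labels <- as.character(labels)
  n <- nrow(coords)
  if (k >= n) stop("k must be smaller than the number of cells")
  nn <- RANN::nn2(coords, coords, k = k + 1L)
  idx <- nn$nn.idx[, -1, drop = FALSE]
  same <- matrix(labels[idx], n, k) == labels
  1 - sum(same) / (n * k)
}

#' Macro-averaged F1 score
#'
#' Unweighted mean over classes of the per-class F1
#' (`2 TP / (2 TP + FP + FN)`; 0 when that denominator is 0). Classes are
#' the union of labels observed in either vector.
#'
#' @param trueLabels,predictedLabels aligned per-cell label vectors.
#' @return number in \[0, 1\].
#' @export
f1Macro <- function(trueLabels, predictedLabels) {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must be aligned (equal length)")
  tl <- as.character(trueLabels)
  pl <- as.character(predictedLabels)
  classes <- sort(union(unique(tl), unique(pl)))
  f1 <- vapply(classes, function(cl) {
    tp <- sum(tl == cl & pl == cl)
    fp <- sum(tl != cl & pl == cl)
    fn <- sum(tl == cl & pl != cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}

#' Full integration-quality report
#'
#' Convenience wrapper computing the whole metric suite for an embedding
#' with batch and type labels: Leiden clustering of the latent coordinates
#' for ARI/NMI against the type labels, a seeded UMAP for silhouette,
#' batch-entropy mixing and iLISI/cLISI (the convention used throughout:
#' clustering-based scores on latent coordinates, neighbourhood scores on
#' the 2-D UMAP), and the over-correction score on the latent coordinates.
#'
#' @param emb a labelled [LatentEmbedding-class].
#' @param resolution Leiden resolution (default 0.5).
#' @param k neighbourhood size for the over-correction score.
#' @param seed integer seed used for clustering, UMAP and probe sampling.
#' @return list of scalar metrics plus `clusters` and `umap`.
#' @export
metricReport <- function(emb, resolution = 0.5, k = 30L, seed = 0L) {
  stopifnot(methods::is(emb, "LatentEmbedding"))
  types <- cellTypeLabels(emb)
  if (is.null(types)) stop("metricReport requires cell-type labels")
  batch <- batchLabels(emb)
  lat <- latentCoords(emb)
  clusters <- clusterLatent(emb, resolution = resolution, seed = seed)
  um <- umapEmbed(emb, seed = seed)
  bem <- if (nlevels(batch) >= 2)
    batchEntropyMixing(um, batch, cellType = types, seed = seed)
  else list(raw = NA_real_, rescaled = NA_real_)
  ilisi <- if (nlevels(batch) >= 2) lisiScore(um, batch)$mean else NA_real_
  list(
    ari = adjustedRandIndex(types, clusters),
    nmi = normalizedMutualInfo(types, clusters),
    silhouette = silhouetteOnEmbedding(um, types),
    batch_entropy_raw = bem$raw,
    batch_entropy_rescaled = bem$rescaled,
    ilisi = ilisi,
    clisi = lisiScore(um, types)$mean,
    over_correction = overCorrectionScore(lat, types, k = min(k, nrow(lat) - 1L)),
    n_clusters = nlevels(clusters),
    clusters = clusters,
    umap = um
  )
}
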