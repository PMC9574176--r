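#' Project cells through the frozen encoder
#'
#' Pushes (new or training) scaled data through the trained encoder in eval
#' mode and returns the posterior means -- the cells' coordinates in the
#' common embedding space. The model is strictly read-only: no weight or
#' running statistic is touched, and the decoder and domain dictionary are
#' never consulted, so new batches need no registration of any kind. This
#' is the online-integration step.
#'
#' @param model a trained [CellBridgeModel-class].
#' @param scaled a [ScaledCells-class] whose feature vocabulary equals the
#'   model's (use [alignProjectionFeatures()] for new data).
#' @param source tag for the resulting embedding, `"projected"` (default)
#'   or `"reference"`.
#' @return a [LatentEmbedding-class].
#' @export
projectCells <- function(model, scaled, source = "projected") {
  stopifnot(methods::is(model, "CellBridgeModel"),
            methods::is(scaled, "ScaledCells"))
  if (!identical(model@version, "cellbridge-model-1"))
    stop("incompatible model version: ", model@version)
  if (model@config$variant == "encoder_with_batch")
    stop("the 'encoder_with_batch' ablation variant cannot project new ",
         "data (its encoder requires training-batch labels)")
  feats <- featureIds(scaled)
  if (!identical(feats, model@features)) {
    missing <- setdiff(model@features, feats)
    extra <- setdiff(feats, model@features)
    stop("feature vocabulary mismatch: ", length(missing),
         " model features missing, ", length(extra),
         " unknown features; run alignProjectionFeatures() first")
  }
  mu <- encodeCells(scaledValues(scaled), model, mode = "eval")$mu
  rownames(mu) <- rownames(scaledValues(scaled))
  methods::new("LatentEmbedding", coords = mu, batch = batchLabels(scaled),
               cellType = cellTypeLabels(scaled), source = source)
}

#' Embedding of the training data
#'
#' Convenience accessor returning the stored eval-mode latent coordinates
#' of the cells the model was trained on, as a [LatentEmbedding-class].
#'
#' @param model a trained [CellBridgeModel-class].
#' @param scaled the training [ScaledCells-class] (for batch/type labels).
#' @return a [LatentEmbedding-class] with `source = "reference"`.
#' @export
referenceEmbedding <- function(model, scaled) {
  methods::new("LatentEmbedding", coords = model@latent,
               batch = batchLabels(scaled),
               cellType = cellTypeLabels(scaled), source = "reference")
}

#' Transfer cell-type labels from a reference to query cells
#'
#' Each query cell receives the majority label among its `k` nearest
#' reference cells (Euclidean distance in the shared embedding). Ties are
#' broken in favour of the tied label with the smallest summed neighbour
#' distance, then lexicographically. When the query IS the reference (same
#' coordinates), each cell's own entry is excluded from its neighbour list
#' unless `excludeSelf = FALSE`.
#'
#' @param reference a labelled [LatentEmbedding-class].
#' @param query a [LatentEmbedding-class] (or coordinate matrix).
#' @param k number of neighbours (default 30).
#' @param excludeSelf logical or `NULL` (auto-detect identical sets).
#' @return data.frame: `cell_id`, `predicted` (factor over the reference
#'   label set), `confidence` (vote fraction in (0, 1\]).
#' @export
transferLabels <- function(reference, query, k = 30L, excludeSelf = NULL) {
  stopifnot(methods::is(reference, "LatentEmbedding"))
  refLab <- cellTypeLabels(reference)
  if (is.null(refLab)) stop("reference embedding carries no cell-type labels")
  refX <- latentCoords(reference)
  qX <- if (methods::is(query, "LatentEmbedding")) latentCoords(query)
        else as.matrix(query)
  if (is.null(excludeSelf))
    excludeSelf <- identical(dim(refX), dim(qX)) &&
      isTRUE(all.equal(unname(refX), unname(qX)))
  if (k < 1) stop("k must be >= 1")
  if (k > nrow(refX) - excludeSelf)
    stop("k = ", k, " exceeds the usable reference size")
  nn <- RANN::nn2(refX, qX, k = k + excludeSelf)
  idx <- nn$nn.idx
  dists <- nn$nn.dists
  if (excludeSelf) { idx <- idx[, -1, drop = FALSE]
                     dists <- dists[, -1, drop = FALSE] }
  labs <- levels(refLab)
  pred <- character(nrow(qX))
  conf <- numeric(nrow(qX))
  for (i in seq_len(nrow(qX))) {
    li <- refLab[idx[i, ]]
    votes <- table(li)
    topVotes <- names(votes)[votes == max(votes)]
    if (length(topVotes) > 1) {
      dsum <- vapply(topVotes,
                     function(l) sum(dists[i, li == l]), numeric(1))
      topVotes <- topVotes[dsum == min(dsum)]
      topVotes <- sort(topVotes)[1]
    }
    pred[i] <- topVotes
    conf[i] <- max(votes) / k
  }
  data.frame(cell_id = rownames(qX) %||% paste0("cell", seq_len(nrow(qX))),
             predicted = factor(pred, levels = labs),
             confidence = conf)
}

#' Cell-type similarity matrix between two batches
#'
#' For a chosen pair of batches, computes the Pearson correlation between
#' the latent centroid of each cell type in the first batch and each cell
#' type in the second. Well-integrated common types show a bright diagonal.
#'
#' @param emb a labelled [LatentEmbedding-class] covering both batches.
#' @param batchPair character vector of two batch labels.
#' @return matrix `S` with `S[i, j]` the correlation between type `i`'s
#'   centroid in the first batch and type `j`'s in the second; values in
#'   \[-1, 1\]. Types absent from a batch are omitted from that axis.
#' @export
similarityMatrix <- function(emb, batchPair) {
  stopifnot(methods::is(emb, "LatentEmbedding"), length(batchPair) == 2)
  lab <- cellTypeLabels(emb)
  if (is.null(lab)) stop("embedding carries no cell-type labels")
  bt <- batchLabels(emb)
  coords <- latentCoords(emb)
  centroids <- function(b) {
    keep <- bt == b
    tl <- droplevels(lab[keep])
    t(vapply(levels(tl),
             function(l) colMeans(coords[keep, , drop = FALSE][tl == l, ,
                                                               drop = FALSE]),
             numeric(ncol(coords))))
  }
  c1 <- centroids(batchPair[1])
  c2 <- centroids(batchPair[2])
  S <- matrix(NA_real_, nrow(c1), nrow(c2),
              dimnames = list(rownames(c1), rownames(c2)))
  for (i in seq_len(nrow(c1)))
    for (j in seq_len(nrow(c2)))
      S[i, j] <- cor(c1[i, ], c2[j, ])
  S
}

#' Row-percent confusion matrix of predicted vs true labels
#'
#' `C[i, j]` is the percentage of cells known to be type `i` that were
#' predicted type `j`; every row sums to 100. Rows for types with zero true
#' cells are excluded.
#'
#' @param trueLabels,predictedLabels aligned per-cell label vectors.
#' @return numeric matrix in percent, rows = true types, columns = the
#'   union of observed labels.
#' @export
confusionMatrix <- function(trueLabels, predictedLabels) {
  if (length(trueLabels) != length(predictedLabels))
    stop("label vectors must be aligned (equal length)")
  tl <- factor(trueLabels)
  pl <- factor(predictedLabels,
               levels = union(levels(factor(predictedLabels)), levels(tl)))
  tab <- unclass(table(tl, pl))
  names(dimnames(tab)) <- NULL
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  100 * sweep(tab, 1, rowSums(tab), "/")
}

#' Leiden clustering of an embedding
#'
#' Builds the (undirected, unweighted) k-nearest-neighbour graph of the
#' latent coordinates (Euclidean) and runs Leiden community detection with
#' the modularity objective at the given resolution. Seeded and
#' deterministic: a fixed seed gives identical labels across runs.
#'
#' @param emb a [LatentEmbedding-class] or coordinate matrix.
#' @param resolution Leiden resolution (default 0.5).
#' @param nNeighbors neighbours in the graph (default 30; reduced with a
#'   warning when there are fewer cells).
#' @param seed integer seed.
#' @return factor of cluster labels, one per cell.
#' @export
clusterLatent <- function(emb, resolution = 0.5, nNeighbors = 30L,
                          seed = 0L) {
  coords <- if (methods::is(emb, "LatentEmbedding")) latentCoords(emb)
            else as.matrix(emb)
  n <- nrow(coords)
  if (n < 2) stop("clustering requires at least 2 cells")
  if (nNeighbors >= n) {
    warning("nNeighbors reduced to ", n - 1, " (only ", n, " cells)")
    nNeighbors <- n - 1L
  }
  if (sum(apply(coords, 2, sd)) == 0) {
    warning("all coordinates identical; returning a single cluster")
    return(factor(rep("0", n)))
  }
  nn <- RANN::nn2(coords, coords, k = nNeighbors + 1L)
  # Jaccard-weighted shared-nearest-neighbour graph (the construction the
  # field's standard toolkits feed to Leiden); weak edges pruned at 1/15
  nbr <- nn$nn.idx                       # includes self in column 1
  edges <- cbind(rep(seq_len(n), nNeighbors),
                 as.vector(nbr[, -1, drop = FALSE]))
  edges <- unique(t(apply(edges, 1, sort)))
  nbrSets <- lapply(seq_len(n), function(i) nbr[i, ])
  jac <- vapply(seq_len(nrow(edges)), function(e) {
    a <- nbrSets[[edges[e, 1]]]
    b <- nbrSets[[edges[e, 2]]]
    ov <- length(intersect(a, b))
    ov / (2 * (nNeighbors + 1L) - ov)
  }, numeric(1))
  keep <- jac >= 1 / 15
  g <- igraph::graph_from_edgelist(edges[keep, , drop = FALSE],
                                   directed = FALSE)
  g <- igraph::set_edge_attr(g, "weight", value = jac[keep])
  if (igraph::vcount(g) < n)
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               weights = igraph::E(g)$weight,
                               resolution = resolution, n_iterations = 5)
  factor(igraph::membership(cl))
}

#' UMAP of an embedding
#'
#' Two-dimensional UMAP of the latent coordinates (Euclidean metric,
#' `n_neighbors = 30`, `min_dist = 0.1` by default), seeded for
#' reproducibility. Used for visualization and as the input space of the
#' silhouette, batch-entropy and LISI metrics.
#'
#' @param emb a [LatentEmbedding-class] or coordinate matrix.
#' @param nNeighbors,minDist UMAP parameters.
#' @param seed integer seed.
#' @return cells x 2 coordinate matrix.
#' @export
umapEmbed <- function(emb, nNeighbors = 30L, minDist = 0.1, seed = 0L) {
  coords <- if (methods::is(emb, "LatentEmbedding")) latentCoords(emb)
            else as.matrix(emb)
  n <- nrow(coords)
  if (n < 3) stop("UMAP requires at least 3 cells")
  if (nNeighbors >= n) {
    warning("nNeighbors reduced to ", n - 1, " (only ", n, " cells)")
    nNeighbors <- n - 1L
  }
  set.seed(seed)
  um <- uwot::umap(coords, n_neighbors = nNeighbors, min_dist = minDist,
                   metric = "euclidean", n_threads = 1, n_sgd_threads = 0)
  rownames(um) <- rownames(coords)
  um
}

#' PCA embedding of scaled data (unintegrated baseline)
#'
#' Top principal components of the scaled value matrix, wrapped as a
#' [LatentEmbedding-class]. This is the conventional "before integration"
#' representation used to quantify raw batch effects.
#'
#' @param scaled a [ScaledCells-class].
#' @param nComponents number of components (default 10).
#' @return a [LatentEmbedding-class] with `source = "reference"`.
#' @export
pcaEmbed <- function(scaled, nComponents = 10L) {
  stopifnot(methods::is(scaled, "ScaledCells"))
  v <- scaledValues(scaled)
  nComponents <- min(nComponents, ncol(v), nrow(v) - 1L)
  pc <- prcomp(v, center = TRUE, scale. = FALSE, rank. = nComponents)
  methods::new("LatentEmbedding", coords = pc$x,
               batch = batchLabels(scaled),
               cellType = cellTypeLabels(scaled), source = "reference")
}
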