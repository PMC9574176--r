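#' Preprocessing parameters
#'
#' Bundles the filtering, normalization and feature-selection settings of
#' the preprocessing recipes. Defaults follow the standard recipe for each
#' modality: RNA keeps cells with >= 600 expressed genes and genes present
#' in >= 3 cells, total-normalizes each cell to 10,000 counts, log1p
#' transforms, and keeps the top 2,000 highly variable genes; ATAC binarizes,
#' drops features present in < 3 cells, keeps the 30,000 most variable
#' peaks/bins, and total-normalizes each cell to the median total. Both end
#' by scaling every feature to \[0, 1\] within each batch (max-abs scaling).
#'
#' @param modality `"rna"` or `"atac"`.
#' @param minGenesPerCell minimum expressed features per cell (RNA filter).
#' @param minCellsPerGene minimum cells a feature must appear in.
#' @param targetSum per-cell total after normalization; the string
#'   `"median"` means the median of the observed totals (ATAC default).
#' @param nTopFeatures number of variable features to keep.
#' @return list of class `preprocessParams`.
#' @export
preprocessParams <- function(modality = c("rna", "atac"),
                             minGenesPerCell = if (modality == "rna") 600L else 0L,
                             minCellsPerGene = 3L,
                             targetSum = if (modality == "rna") 1e4 else "median",
                             nTopFeatures = if (modality == "rna") 2000L else 30000L) {
  modality <- match.arg(modality)
  stopifnot(minGenesPerCell >= 0, minCellsPerGene >= 0, nTopFeatures >= 1)
  structure(list(modality = modality,
                 minGenesPerCell = as.integer(minGenesPerCell),
                 minCellsPerGene = as.integer(minCellsPerGene),
                 targetSum = targetSum,
                 nTopFeatures = as.integer(nTopFeatures)),
            class = "preprocessParams")
}

.as_counts_input <- function(x, batch, cellType) {
  if (methods::is(x, "SummarizedExperiment")) {
    cd <- SummarizedExperiment::colData(x)
    if (is.null(batch) && "batch" %in% colnames(cd)) batch <- cd$batch
    if (is.null(cellType) && "cell_type" %in% colnames(cd))
      cellType <- cd$cell_type
    x <- SummarizedExperiment::assay(x, "counts")
  }
  if (is.null(batch)) stop("batch labels are required")
  x <- methods::as(x, "CsparseMatrix")
  if (is.null(rownames(x))) rownames(x) <- paste0("feature", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("cell", seq_len(ncol(x)))
  if (length(x@x) && min(x@x) < 0)
    stop("counts must be non-negative")
  batch <- factor(batch)
  if (length(batch) != ncol(x))
    stop("batch labels must have one entry per cell")
  if (!is.null(cellType)) {
    cellType <- factor(cellType)
    if (length(cellType) != ncol(x))
      stop("cell-type labels must have one entry per cell")
  }
  list(counts = x, batch = batch, cellType = cellType)
}

# Per-batch dispersion-based HVG selection on log-normalized values.
# Within each batch: dispersion = var/mean of expm1(log values), z-scored
# within 20 mean-quantile bins; a gene is 'variable in that batch' if it
# ranks in the top nTop by normalized dispersion. Genes are then ordered by
# (number of batches variable in, mean normalized dispersion).
.select_hvg <- function(lognorm, batch, nTop) {
  G <- nrow(lognorm)
  nB <- nlevels(batch)
  nTop <- min(nTop, G)
  hvCount <- integer(G)
  dispSum <- numeric(G)
  for (b in levels(batch)) {
    xb <- expm1(lognorm[, batch == b, drop = FALSE])
    mu <- Matrix::rowMeans(xb)
    m2 <- Matrix::rowMeans(xb^2)
    v <- (m2 - mu^2) * ncol(xb) / max(1, ncol(xb) - 1)
    disp <- ifelse(mu > 0, v / mu, 0)
    # normalize dispersions within mean bins so selection is not driven by
    # expression level
    bins <- cut(mu, breaks = unique(quantile(mu, probs = seq(0, 1, 0.05))),
                include.lowest = TRUE)
    nd <- disp
    for (lv in levels(bins)) {
      i <- which(bins == lv)
      s <- sd(disp[i])
      nd[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
    }
    hvCount[order(nd, decreasing = TRUE)[seq_len(nTop)]] <-
      hvCount[order(nd, decreasing = TRUE)[seq_len(nTop)]] + 1L
    dispSum <- dispSum + nd
  }
  order(hvCount, dispSum / nB, decreasing = TRUE)[seq_len(nTop)]
}

# Per-batch max-abs scaling of a cells x features matrix into [0, 1].
# Returns the scaled matrix and the batches x features divisor record
# (divisor 1 where a feature is all-zero in a batch).
.maxabs_by_batch <- function(m, batch) {
  rec <- matrix(1, nlevels(batch), ncol(m),
                dimnames = list(levels(batch), colnames(m)))
  for (b in levels(batch)) {
    i <- which(batch == b)
    mx <- apply(abs(m[i, , drop = FALSE]), 2, max)
    div <- ifelse(mx > 0, mx, 1)
    rec[b, ] <- div
    m[i, ] <- sweep(m[i, , drop = FALSE], 2, div, "/")
  }
  list(values = m, record = rec)
}

#' Preprocess raw scRNA-seq counts into model-ready scaled values
#'
#' Applies, in order: (i) drop cells expressing fewer than
#' `minGenesPerCell` genes, then genes present in fewer than
#' `minCellsPerGene` of the surviving cells; (ii) scale each cell's counts
#' to a total of `targetSum`; (iii) log-transform with offset 1; (iv) keep
#' the `nTopFeatures` most highly variable genes, selected per batch and
#' combined (genes ranked by the number of batches in which they are highly
#' variable, ties by mean normalized dispersion); (v) scale every gene to
#' \[0, 1\] within each batch by its per-batch maximum.
#'
#' @param x a `SingleCellExperiment` with a `counts` assay (and `batch` /
#'   `cell_type` colData), or a features x cells (sparse) matrix.
#' @param batch per-cell batch labels (taken from `colData` if omitted).
#' @param cellType optional per-cell type labels.
#' @param params a [preprocessParams()] with `modality = "rna"`.
#' @return a [ScaledCells-class] (cells x features).
#' @examples
#' sce <- simulateMultibatch(simSpec(nTypes = 3, nBatches = 2,
#'   cellsPerTypePerBatch = 30, nFeatures = 80, seed = 1))
#' sc <- preprocessRNA(sce, params = preprocessParams("rna",
#'   minGenesPerCell = 5, nTopFeatures = 40))
#' range(scaledValues(sc))
#' @export
preprocessRNA <- function(x, batch = NULL, cellType = NULL,
                          params = preprocessParams("rna")) {
  stopifnot(inherits(params, "preprocessParams"))
  if (params$modality != "rna")
    stop("preprocessRNA requires params with modality 'rna'")
  inp <- .as_counts_input(x, batch, cellType)
  counts <- inp$counts

  # (i) cell and gene filters
  genesPerCell <- Matrix::colSums(counts > 0)
  keepCells <- genesPerCell >= params$minGenesPerCell
  if (!any(keepCells))
    stop("all cells filtered out (min ", params$minGenesPerCell,
         " expressed genes per cell)")
  counts <- counts[, keepCells, drop = FALSE]
  cellsPerGene <- Matrix::rowSums(counts > 0)
  keepGenes <- cellsPerGene >= params$minCellsPerGene
  if (!any(keepGenes))
    stop("all genes filtered out (min ", params$minCellsPerGene,
         " cells per gene)")
  counts <- counts[keepGenes, , drop = FALSE]
  batchF <- droplevels(inp$batch[keepCells])
  typeF <- if (is.null(inp$cellType)) NULL else
    droplevels(inp$cellType[keepCells])

  # (ii) total-count normalization, (iii) log1p
  totals <- Matrix::colSums(counts)
  if (any(totals == 0)) stop("cells with zero total counts survived filtering")
  lognorm <- log1p(t(t(counts) * (params$targetSum / totals)))

  # (iv) batch-aware HVG selection
  sel <- sort(.select_hvg(lognorm, batchF, params$nTopFeatures))
  m <- t(as.matrix(lognorm[sel, , drop = FALSE]))   # cells x features

  # (v) per-batch max-abs scaling
  sc <- .maxabs_by_batch(m, batchF)
  methods::new("ScaledCells", values = sc$values, batch = batchF,
               cellType = typeF, scalingRecord = sc$record,
               params = unclass(params))
}

#' Preprocess raw scATAC-seq counts into model-ready scaled values
#'
#' Applies, in order: (i) binarize (any positive count becomes 1); (ii) drop
#' features present in fewer than `minCellsPerGene` cells; (iii) keep the
#' `nTopFeatures` most variable peaks/bins (by variance of the binarized
#' values); (iv) scale each cell's total to the median of all cells'
#' totals; (v) per-batch max-abs scaling to \[0, 1\].
#'
#' @inheritParams preprocessRNA
#' @param params a [preprocessParams()] with `modality = "atac"`.
#' @return a [ScaledCells-class] (cells x features).
#' @export
preprocessATAC <- function(x, batch = NULL, cellType = NULL,
                           params = preprocessParams("atac")) {
  stopifnot(inherits(params, "preprocessParams"))
  if (params$modality != "atac")
    stop("preprocessATAC requires params with modality 'atac'")
  inp <- .as_counts_input(x, batch, cellType)
  bin <- inp$counts
  bin@x <- rep(1, length(bin@x))                   # (i) binarize

  cellsPerFeat <- Matrix::rowSums(bin)
  keep <- cellsPerFeat >= params$minCellsPerGene   # (ii) feature filter
  if (!any(keep)) stop("all features filtered out")
  bin <- bin[keep, , drop = FALSE]

  # (iii) most variable features: variance of a Bernoulli feature
  p <- Matrix::rowMeans(bin)
  n <- ncol(bin)
  v <- p * (1 - p) * n / max(1, n - 1)
  nTop <- min(params$nTopFeatures, nrow(bin))
  sel <- sort(order(v, decreasing = TRUE)[seq_len(nTop)])
  bin <- bin[sel, , drop = FALSE]

  # (iv) normalize totals to the median total
  totals <- Matrix::colSums(bin)
  if (any(totals == 0))
    stop("cells with zero accessible features after selection; ",
         "raise nTopFeatures or filter cells upstream")
  target <- if (identical(params$targetSum, "median")) median(totals)
            else params$targetSum
  norm <- t(t(bin) * (target / totals))            # features x cells
  m <- t(as.matrix(norm))                          # cells x features

  sc <- .maxabs_by_batch(m, factor(inp$batch))     # (v)
  methods::new("ScaledCells", values = sc$values, batch = factor(inp$batch),
               cellType = inp$cellType, scalingRecord = sc$record,
               params = unclass(params))
}

#' Align a new batch onto a trained model's feature vocabulary
#'
#' Normalizes a new (projection-time) batch with its modality's recipe, then
#' restricts and reorders its features to the reference vocabulary of a
#' trained model: features absent from the new data are zero-filled, extra
#' features are dropped, and the \[0, 1\] max-abs scaling is computed within
#' the new batch only (projection treats arriving data as a new batch; the
#' reference scaling is never reused).
#'
#' @inheritParams preprocessRNA
#' @param referenceFeatures character: the ordered feature vocabulary of the
#'   trained model (see [featureIds()]).
#' @param params the [preprocessParams()] of the matching modality; cell and
#'   feature filters apply as in training, but feature selection is replaced
#'   by the reference vocabulary.
#' @return a [ScaledCells-class] whose columns equal `referenceFeatures`.
#' @export
alignProjectionFeatures <- function(x, referenceFeatures, batch = NULL,
                                    cellType = NULL,
                                    params = preprocessParams("rna")) {
  stopifnot(is.character(referenceFeatures), length(referenceFeatures) >= 1)
  inp <- .as_counts_input(x, batch, cellType)
  counts <- inp$counts
  overlap <- intersect(rownames(counts), referenceFeatures)
  if (!length(overlap))
    stop("no overlap between new features and the reference vocabulary ",
         "(0 of ", length(referenceFeatures), " reference features present)")

  if (params$modality == "rna") {
    genesPerCell <- Matrix::colSums(counts > 0)
    keepCells <- genesPerCell >= params$minGenesPerCell
    if (!any(keepCells)) stop("all cells filtered out")
    counts <- counts[, keepCells, drop = FALSE]
    totals <- Matrix::colSums(counts)
    if (any(totals == 0)) stop("cells with zero total counts")
    norm <- log1p(t(t(counts) * (params$targetSum / totals)))
    batchF <- droplevels(factor(inp$batch[keepCells]))
    typeF <- if (is.null(inp$cellType)) NULL else
      droplevels(inp$cellType[keepCells])
    m <- matrix(0, ncol(norm), length(referenceFeatures),
                dimnames = list(colnames(norm), referenceFeatures))
    m[, overlap] <- t(as.matrix(norm[overlap, , drop = FALSE]))
  } else {
    bin <- counts
    bin@x <- rep(1, length(bin@x))
    batchF <- factor(inp$batch)
    typeF <- inp$cellType
    m <- matrix(0, ncol(bin), length(referenceFeatures),
                dimnames = list(colnames(bin), referenceFeatures))
    m[, overlap] <- t(as.matrix(bin[overlap, , drop = FALSE]))
    totals <- rowSums(m)
    if (any(totals == 0))
      stop("cells with zero accessible reference features")
    target <- if (identical(params$targetSum, "median")) median(totals)
              else params$targetSum
    m <- m * (target / totals)
  }
  sc <- .maxabs_by_batch(m, batchF)
  methods::new("ScaledCells", values = sc$values, batch = batchF,
               cellType = typeF, scalingRecord = sc$record,
               params = c(unclass(params), list(aligned = TRUE,
                                                nOverlap = length(overlap))))
}
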