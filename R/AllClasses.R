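#' @import methods
#' @importFrom stats median prcomp rnorm runif rbinom rnbinom sd var cor setNames quantile dist
#' @importFrom utils head
#' @importFrom Matrix t colSums rowSums colMeans rowMeans
NULL

setClassUnion("factorOrNULL", c("factor", "NULL"))

#' ScaledCells: preprocessed model-ready single-cell data
#'
#' Holds a cell x feature matrix of values scaled into \[0, 1\] over a fixed,
#' ordered feature vocabulary, together with the per-cell batch labels,
#' optional cell-type labels, the per-(batch, feature) scaling divisors used
#' (needed to document how projection-time batches were scaled), and the
#' preprocessing parameters that produced it.
#'
#' Rows are cells, columns are features -- the orientation the model
#' consumes. Use [scaledValues()], [batchLabels()], [cellTypeLabels()],
#' [featureIds()] and [scalingRecord()] to access the slots.
#'
#' @slot values numeric matrix, cells x features, all entries in \[0, 1\].
#' @slot batch factor of length `nrow(values)`.
#' @slot cellType optional factor of length `nrow(values)` or `NULL`.
#' @slot scalingRecord numeric matrix, batches x features: the divisor
#'   applied to each (batch, feature) pair (1 where the observed maximum was
#'   zero, so all-zero features stay zero).
#' @slot params list: the preprocessing parameters applied (provenance).
#'
#' @seealso [preprocessRNA()], [preprocessATAC()], [alignProjectionFeatures()]
#' @export
setClass("ScaledCells",
  slots = c(
    values = "matrix",
    batch = "factor",
    cellType = "factorOrNULL",
    scalingRecord = "matrix",
    params = "list"
  )
)

setValidity("ScaledCells", function(object) {
  v <- object@values
  msg <- character()
  if (length(v) && (anyNA(v) || min(v) < 0 || max(v) > 1 + 1e-12))
    msg <- c(msg, "all scaled values must lie in [0, 1]")
  if (length(object@batch) != nrow(v))
    msg <- c(msg, "batch labels must match the number of cells (rows)")
  if (!is.null(object@cellType) && length(object@cellType) != nrow(v))
    msg <- c(msg, "cellType labels must match the number of cells (rows)")
  if (is.null(colnames(v)) || anyDuplicated(colnames(v)))
    msg <- c(msg, "feature ids (column names) must be present and unique")
  if (!identical(dim(object@scalingRecord),
                 c(nlevels(object@batch), ncol(v))))
    msg <- c(msg, "scalingRecord must be batches x features")
  if (length(msg)) msg else TRUE
})

#' CellBridgeModel: trained integration model
#'
#' All learned state of the variational autoencoder: the batch-free encoder
#' (one 1024-unit hidden layer with batch normalization and ReLU, then two
#' linear heads for the posterior mean and log-variance), and the one-layer
#' decoder (linear map from the latent space back to feature space, followed
#' by domain-specific batch normalization and a sigmoid). The encoder never
#' receives batch labels; only the decoder's DSBN layer is indexed by the
#' training batch (domain) label, which is what makes the encoder reusable
#' on unseen batches without retraining.
#'
#' @slot config list, see [modelConfig()].
#' @slot encoder list: `W1`, `b1`, `bn` (gamma/beta/mean/var), `Wmu`, `bmu`,
#'   `Wlv`, `blv`.
#' @slot decoder list: `W`, `b`, `dsbn` with per-domain affine parameters and
#'   running statistics (matrices with one row per domain).
#' @slot domains character: training batch labels, in dictionary order.
#' @slot features character: the ordered feature vocabulary the model expects.
#' @slot trainLog data.frame with one row per epoch (losses, iterations).
#' @slot latent matrix: eval-mode posterior means of the training cells.
#' @slot version character: serialization format tag.
#' @seealso [fitModel()], [projectCells()], [saveModel()]
#' @export
setClass("CellBridgeModel",
  slots = c(
    config = "list",
    encoder = "list",
    decoder = "list",
    domains = "character",
    features = "character",
    trainLog = "data.frame",
    latent = "matrix",
    version = "character"
  )
)

setValidity("CellBridgeModel", function(object) {
  msg <- character()
  cfg <- object@config
  if (!length(object@domains)) msg <- c(msg, "at least one training domain required")
  if (length(object@features) != cfg$nFeatures)
    msg <- c(msg, "feature vocabulary length must equal config$nFeatures")
  if (any(object@encoder$bn$var < 0))
    msg <- c(msg, "encoder running variances must be non-negative")
  if (any(object@decoder$dsbn$var < 0))
    msg <- c(msg, "DSBN running variances must be non-negative")
  if (length(msg)) msg else TRUE
})

#' LatentEmbedding: cells in the common embedding space
#'
#' Posterior-mean coordinates of cells in the shared low-dimensional space,
#' either from the original training data (`source = "reference"`) or from a
#' new batch pushed through the frozen encoder (`source = "projected"`).
#'
#' @slot coords numeric matrix, cells x latent dimensions.
#' @slot batch factor of per-cell batch labels.
#' @slot cellType optional factor of per-cell type labels, or `NULL`.
#' @slot source character, `"reference"` or `"projected"`.
#' @seealso [projectCells()], [transferLabels()], [clusterLatent()]
#' @export
setClass("LatentEmbedding",
  slots = c(
    coords = "matrix",
    batch = "factor",
    cellType = "factorOrNULL",
    source = "character"
  )
)

setValidity("LatentEmbedding", function(object) {
  msg <- character()
  if (length(object@coords) && !all(is.finite(object@coords)))
    msg <- c(msg, "latent coordinates must be finite")
  if (length(object@batch) != nrow(object@coords))
    msg <- c(msg, "batch labels must match the number of cells")
  if (!is.null(object@cellType) &&
      length(object@cellType) != nrow(object@coords))
    msg <- c(msg, "cellType labels must match the number of cells")
  if (!object@source %in% c("reference", "projected"))
    msg <- c(msg, "source must be 'reference' or 'projected'")
  if (length(msg)) msg else TRUE
})
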