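# Accessor generics for the package's S4 classes. Slot access from user code
# should always go through these.

#' @export
setGeneric("scaledValues", function(x) standardGeneric("scaledValues"))
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))
#' @export
setGeneric("cellTypeLabels", function(x) standardGeneric("cellTypeLabels"))
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))
#' @export
setGeneric("scalingRecord", function(x) standardGeneric("scalingRecord"))
#' @export
setGeneric("preprocessProvenance", function(x) standardGeneric("preprocessProvenance"))
#' @export
setGeneric("modelConfigOf", function(x) standardGeneric("modelConfigOf"))
#' @export
setGeneric("domainLabels", function(x) standardGeneric("domainLabels"))
#' @export
setGeneric("trainLog", function(x) standardGeneric("trainLog"))
#' @export
setGeneric("latentCoords", function(x) standardGeneric("latentCoords"))
#' @export
setGeneric("embeddingSource", function(x) standardGeneric("embeddingSource"))

#' Access the scaled value matrix (cells x features)
#' @param x a [ScaledCells-class] object
#' @return numeric matrix of values in \[0, 1\]
#' @export
setMethod("scaledValues", "ScaledCells", function(x) x@values)

#' @describeIn scaledValues batch labels per cell
#' @export
setMethod("batchLabels", "ScaledCells", function(x) x@batch)
#' @export
setMethod("batchLabels", "LatentEmbedding", function(x) x@batch)

#' @describeIn scaledValues optional cell-type labels per cell
#' @export
setMethod("cellTypeLabels", "ScaledCells", function(x) x@cellType)
#' @export
setMethod("cellTypeLabels", "LatentEmbedding", function(x) x@cellType)

#' @describeIn scaledValues ordered feature vocabulary
#' @export
setMethod("featureIds", "ScaledCells", function(x) colnames(x@values))
#' @export
setMethod("featureIds", "CellBridgeModel", function(x) x@features)

#' @describeIn scaledValues per-(batch, feature) scaling divisors
#' @export
setMethod("scalingRecord", "ScaledCells", function(x) x@scalingRecord)

#' @describeIn scaledValues preprocessing parameters applied (provenance)
#' @export
setMethod("preprocessProvenance", "ScaledCells", function(x) x@params)

#' Model accessors
#' @param x a [CellBridgeModel-class]
#' @return `modelConfigOf`: the config list; `domainLabels`: training batch
#'   labels; `trainLog`: per-epoch training record.
#' @export
setMethod("modelConfigOf", "CellBridgeModel", function(x) x@config)
#' @export
setMethod("domainLabels", "CellBridgeModel", function(x) x@domains)
#' @export
setMethod("trainLog", "CellBridgeModel", function(x) x@trainLog)

#' Latent coordinate accessors
#' @param x a [LatentEmbedding-class] or [CellBridgeModel-class]
#' @return numeric matrix of latent coordinates (posterior means)
#' @export
setMethod("latentCoords", "LatentEmbedding", function(x) x@coords)
#' @export
setMethod("latentCoords", "CellBridgeModel", function(x) x@latent)
#' @export
setMethod("embeddingSource", "LatentEmbedding", function(x) x@source)

setMethod("show", "ScaledCells", function(object) {
  cat("ScaledCells:", nrow(object@values), "cells x",
      ncol(object@values), "features\n")
  cat("  batches:", paste(levels(object@batch), collapse = ", "), "\n")
  if (!is.null(object@cellType))
    cat("  cell types:", nlevels(object@cellType), "\n")
  cat("  modality:", object@params$modality %||% "unknown", "\n")
  invisible(object)
})

setMethod("show", "CellBridgeModel", function(object) {
  cfg <- object@config
  cat("CellBridgeModel (variant:", cfg$variant, ")\n")
  cat("  ", cfg$nFeatures, " features -> ", cfg$hiddenDim, " hidden -> ",
      cfg$latentDim, " latent; beta = ", cfg$beta, "\n", sep = "")
  cat("  domains:", paste(object@domains, collapse = ", "), "\n")
  if (nrow(object@trainLog))
    cat("  trained ", nrow(object@trainLog), " epochs (",
        object@trainLog$iterations[nrow(object@trainLog)], " iterations), ",
        "stop: ", attr(object@trainLog, "stopReason") %||% "?", "\n", sep = "")
  invisible(object)
})

setMethod("show", "LatentEmbedding", function(object) {
  cat("LatentEmbedding (", object@source, "): ", nrow(object@coords),
      " cells x ", ncol(object@coords), " dims\n", sep = "")
  invisible(object)
})

`%||%` <- function(a, b) if (is.null(a)) b else a
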