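#' Save / load a trained model
#'
#' A model is stored as a single-file archive (RDS) with a versioned header
#' so that projection can refuse models written by an incompatible format.
#' The archive contains the config, feature vocabulary, domain dictionary,
#' all weights and running statistics, and the training log.
#'
#' @param model a [CellBridgeModel-class].
#' @param path file path to write/read.
#' @return `saveModel` returns `path` invisibly; `loadModel` returns the
#'   model.
#' @export
saveModel <- function(model, path) {
  stopifnot(methods::is(model, "CellBridgeModel"))
  saveRDS(list(format = "cellbridge-model", version = model@version,
               model = model), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "cellbridge-model"))
    stop("not a cellbridge model archive: ", path)
  if (!identical(obj$version, "cellbridge-model-1"))
    stop("unsupported model version: ", obj$version)
  methods::validObject(obj$model)
  obj$model
}

#' Checksum of a model's complete state
#'
#' MD5 digest of the serialized model, used to verify the frozen-encoder
#' contract: projection must leave the model bit-for-bit unchanged.
#'
#' @param model a [CellBridgeModel-class].
#' @return character MD5 string.
#' @export
modelChecksum <- function(model) {
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  saveRDS(model, f)
  unname(tools::md5sum(f))
}

#' Read a count matrix from MTX / CSV / TSV
#'
#' `readCountsMTX` reads a MatrixMarket triplet directory or file trio
#' (matrix + feature ids + cell barcodes, one id per line); `readCountsCSV`
#' reads a dense delimited table with cells in rows and features in
#' columns. Both return a `SingleCellExperiment` with a sparse `counts`
#' assay; attach batch labels through the `batch` argument or a colData
#' column afterwards.
#'
#' @param matrixFile path to the `.mtx` file.
#' @param featuresFile path to the feature-id file (one per line, first
#'   column used).
#' @param barcodesFile path to the cell-barcode file.
#' @param batch optional per-cell batch labels.
#' @param cellType optional per-cell type labels.
#' @return a `SingleCellExperiment`.
#' @export
readCountsMTX <- function(matrixFile, featuresFile, barcodesFile,
                          batch = NULL, cellType = NULL) {
  m <- methods::as(Matrix::readMM(matrixFile), "CsparseMatrix")
  feats <- read.table(featuresFile, sep = "\t",
                      stringsAsFactors = FALSE)[, 1]
  cells <- read.table(barcodesFile, sep = "\t",
                      stringsAsFactors = FALSE)[, 1]
  if (nrow(m) != length(feats) || ncol(m) != length(cells))
    stop("matrix dimensions (", nrow(m), " x ", ncol(m),
         ") do not match feature/barcode files")
  dimnames(m) <- list(feats, cells)
  .counts_as_sce(m, batch, cellType)
}

#' @rdname readCountsMTX
#' @param file delimited file, cells in rows, header of feature ids.
#' @param sep field separator (default `,`; use `"\t"` for TSV).
#' @export
readCountsCSV <- function(file, sep = ",", batch = NULL, cellType = NULL) {
  df <- read.table(file, sep = sep, header = TRUE, row.names = 1,
                   check.names = FALSE)
  m <- methods::as(t(as.matrix(df)), "CsparseMatrix")  # features x cells
  .counts_as_sce(m, batch, cellType)
}

.counts_as_sce <- function(m, batch, cellType) {
  cd <- S4Vectors::DataFrame(row.names = colnames(m))
  if (!is.null(batch)) cd$batch <- factor(batch)
  if (!is.null(cellType)) cd$cell_type <- factor(cellType)
  SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = m), colData = cd)
}

# ---- minimal H5AD support (requires the suggested rhdf5 package) --------

.need_rhdf5 <- function() {
  if (!requireNamespace("rhdf5", quietly = TRUE))
    stop("H5AD support needs the 'rhdf5' package")
}

.h5_read_frame_column <- function(file, path) {
  obj <- rhdf5::h5read(file, path)
  if (is.list(obj) && all(c("categories", "codes") %in% names(obj))) {
    codes <- as.integer(obj$codes)
    factor(obj$categories[codes + 1L], levels = obj$categories)
  } else as.vector(obj)
}

#' Read a (subset of) an H5AD file into a SingleCellExperiment
#'
#' Supports the common layouts written by current AnnData: dense `X` or CSR
#' sparse `X` (`data`/`indices`/`indptr`), string or categorical `obs`
#' columns. Only `X`, `obs` and `var` names are read.
#'
#' @param path H5AD file.
#' @param batchKey obs column with batch labels (default `"batch"`).
#' @param typeKey obs column with cell types (default `"cell_type"`,
#'   optional).
#' @return a `SingleCellExperiment` (features x cells `counts` assay).
#' @export
readH5AD <- function(path, batchKey = "batch", typeKey = "cell_type") {
  .need_rhdf5()
  ls <- rhdf5::h5ls(path)
  idxName <- function(group) {
    at <- tryCatch(rhdf5::h5readAttributes(path, group), error = function(e) list())
    at[["_index"]] %||% "_index"
  }
  obsIdx <- as.character(rhdf5::h5read(path, paste0("obs/", idxName("obs"))))
  varIdx <- as.character(rhdf5::h5read(path, paste0("var/", idxName("var"))))
  xinfo <- ls[ls$group == "/" & ls$name == "X", ]
  if (nrow(xinfo) && xinfo$otype == "H5I_GROUP") {
    data <- as.numeric(rhdf5::h5read(path, "X/data"))
    indices <- as.integer(rhdf5::h5read(path, "X/indices"))
    indptr <- as.integer(rhdf5::h5read(path, "X/indptr"))
    # AnnData X is cells x features, CSR; as CSC of the transpose it is
    # features x cells directly.
    m <- Matrix::sparseMatrix(i = indices + 1L, p = indptr, x = data,
                              dims = c(length(varIdx), length(obsIdx)))
  } else {
    x <- rhdf5::h5read(path, "X")   # stored row-major; arrives transposed
    m <- methods::as(Matrix::Matrix(x, sparse = TRUE), "CsparseMatrix")
    if (!identical(dim(m), c(length(varIdx), length(obsIdx))))
      m <- Matrix::t(m)
  }
  dimnames(m) <- list(varIdx, obsIdx)
  obsCols <- ls$name[ls$group == "/obs"]
  batch <- if (batchKey %in% obsCols)
    .h5_read_frame_column(path, paste0("obs/", batchKey)) else NULL
  cellType <- if (!is.null(typeKey) && typeKey %in% obsCols)
    .h5_read_frame_column(path, paste0("obs/", typeKey)) else NULL
  .counts_as_sce(m, batch, cellType)
}

#' Write a ScaledCells object to H5AD
#'
#' Writes the scaled matrix as dense `X` (cells x features), the batch and
#' optional cell-type labels as categorical `obs` columns, feature ids as
#' `var`, and the scaling record and preprocessing provenance under `uns`.
#' The file round-trips through [readScaledH5AD()].
#'
#' @param scaled a [ScaledCells-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeScaledH5AD <- function(scaled, path) {
  .need_rhdf5()
  stopifnot(methods::is(scaled, "ScaledCells"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  v <- scaledValues(scaled)
  # transpose: HDF5 is row-major, AnnData expects cells as rows on disk
  rhdf5::h5write(t(v), path, "X")
  rhdf5::h5createGroup(path, "obs")
  rhdf5::h5write(rownames(v) %||% paste0("cell", seq_len(nrow(v))),
                 path, "obs/_index")
  .h5_write_categorical(path, "obs/batch", batchLabels(scaled))
  if (!is.null(cellTypeLabels(scaled)))
    .h5_write_categorical(path, "obs/cell_type", cellTypeLabels(scaled))
  rhdf5::h5createGroup(path, "var")
  rhdf5::h5write(colnames(v), path, "var/_index")
  rhdf5::h5createGroup(path, "uns")
  rhdf5::h5write(scalingRecord(scaled), path, "uns/scaling_record")
  rhdf5::h5write(levels(batchLabels(scaled)), path, "uns/scaling_batches")
  prov <- preprocessProvenance(scaled)
  rhdf5::h5write(as.character(jsonlite::toJSON(prov, auto_unbox = TRUE,
                                               null = "null")),
                 path, "uns/provenance")
  rhdf5::H5close()
  invisible(path)
}

.h5_write_categorical <- function(path, name, f) {
  f <- factor(f)
  rhdf5::h5createGroup(path, name)
  rhdf5::h5write(levels(f), path, paste0(name, "/categories"))
  rhdf5::h5write(as.integer(f) - 1L, path, paste0(name, "/codes"))
}

#' @rdname writeScaledH5AD
#' @export
readScaledH5AD <- function(path) {
  .need_rhdf5()
  x <- rhdf5::h5read(path, "X")                     # features x cells here
  cells <- as.character(rhdf5::h5read(path, "obs/_index"))
  feats <- as.character(rhdf5::h5read(path, "var/_index"))
  m <- t(x)
  if (!identical(dim(m), c(length(cells), length(feats)))) m <- x
  dimnames(m) <- list(cells, feats)
  batch <- .h5_read_frame_column(path, "obs/batch")
  ls <- rhdf5::h5ls(path)
  cellType <- if ("cell_type" %in% ls$name[ls$group == "/obs"])
    .h5_read_frame_column(path, "obs/cell_type") else NULL
  rec <- as.matrix(rhdf5::h5read(path, "uns/scaling_record"))
  dimnames(rec) <- list(as.character(rhdf5::h5read(path,
                                                   "uns/scaling_batches")),
                        feats)
  prov <- jsonlite::fromJSON(as.character(rhdf5::h5read(path,
                                                        "uns/provenance")))
  rhdf5::H5close()
  methods::new("ScaledCells", values = m, batch = factor(batch),
               cellType = if (is.null(cellType)) NULL else factor(cellType),
               scalingRecord = rec, params = as.list(prov))
}

#' @importFrom utils read.table
NULL
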