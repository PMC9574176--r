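#' Optimizer and schedule settings
#'
#' Defaults are the published training recipe: Adam at learning rate 2e-4
#' with 5e-4 weight decay and exponential decay rates (0.9, 0.999),
#' mini-batches of 64 cells drawn at random across all batches, at most
#' 30,000 mini-batch steps, and early stopping when the epoch-mean total
#' loss has not improved by more than `tol` for `patience` consecutive
#' epochs. One epoch is one full pass over all cells. The parameters from
#' the best-loss epoch are returned, not the last.
#'
#' @param lr learning rate.
#' @param weightDecay L2 penalty added to gradients (applied to every
#'   learnable parameter, as in the reference optimizer).
#' @param betas Adam first/second-moment decay rates.
#' @param batchSize mini-batch size.
#' @param maxIterations cap on mini-batch steps.
#' @param patience early-stopping patience in epochs.
#' @param tol minimum loss improvement that resets the patience counter.
#' @param seed integer seed controlling initialization, shuffling, and the
#'   reparameterization draws; identical seeds give bitwise-identical runs
#'   on one platform.
#' @param verbose print a per-epoch loss line to stderr.
#' @return list of class `trainConfig`.
#' @export
trainConfig <- function(lr = 2e-4, weightDecay = 5e-4,
                        betas = c(0.9, 0.999), batchSize = 64L,
                        maxIterations = 30000L, patience = 10L,
                        tol = 1e-4, seed = 0L, verbose = FALSE) {
  stopifnot(lr >= 0, batchSize >= 1, maxIterations >= 1, patience >= 1,
            tol >= 0, length(betas) == 2)
  structure(list(lr = lr, weightDecay = weightDecay, betas = betas,
                 batchSize = as.integer(batchSize),
                 maxIterations = as.integer(maxIterations),
                 patience = as.integer(patience), tol = tol,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "trainConfig")
}

#' Mini-batch index stream for one epoch
#'
#' The default strategy pools cells from ALL batches: one epoch is a seeded
#' random permutation of every cell, chopped into consecutive blocks of
#' `size` (the last block may be smaller). This keeps every mini-batch
#' close to the overall mixture distribution, which is what lets the
#' encoder's batch-norm layer align mini-batch deviations to the global
#' distribution. `byBatch = TRUE` (the `sample_by_batch_no_bn` ablation)
#' instead permutes within each batch and emits single-batch blocks.
#'
#' @param n number of cells (pooled mode).
#' @param size mini-batch size.
#' @param batch per-cell batch factor, required when `byBatch = TRUE`.
#' @param byBatch draw single-batch blocks instead of pooled blocks.
#' @return list of integer index vectors partitioning `1:n`.
#' @export
sampleMinibatches <- function(n, size, batch = NULL, byBatch = FALSE) {
  if (n < 1) stop("no cells to sample")
  if (!byBatch) {
    perm <- sample.int(n)
    split(perm, ceiling(seq_along(perm) / size))
  } else {
    stopifnot(!is.null(batch), length(batch) == n)
    blocks <- list()
    for (b in sample(levels(batch))) {
      idx <- which(batch == b)
      perm <- idx[sample.int(length(idx))]
      blocks <- c(blocks, split(perm, ceiling(seq_along(perm) / size)))
    }
    unname(blocks)
  }
}

# Backward pass of batch normalization (train mode, biased batch variance).
# dy: upstream gradient; cache: from batchNormForward(train).
.bn_backward <- function(dy, cache, gamma, eps) {
  m <- nrow(dy)
  xhat <- cache$xhat
  istd <- 1 / sqrt(cache$batchVar + eps)
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, "*")
  dx <- sweep(dxhat - matrix(colMeans(dxhat), m, ncol(dy), byrow = TRUE) -
                xhat * matrix(colMeans(dxhat * xhat), m, ncol(dy),
                              byrow = TRUE),
              2, istd, "*")
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

.adam_step <- function(p, g, st, lr, betas, wd, t) {
  g <- g + wd * p
  st$m <- betas[1] * st$m + (1 - betas[1]) * g
  st$v <- betas[2] * st$v + (1 - betas[2]) * g^2
  mhat <- st$m / (1 - betas[1]^t)
  vhat <- st$v / (1 - betas[2]^t)
  st$p <- p - lr * mhat / (sqrt(vhat) + 1e-8)
  st
}

#' Fit the integration model
#'
#' Trains the variational autoencoder on preprocessed multi-batch data with
#' mini-batch Adam and patience-based early stopping (see [trainConfig()]).
#' The domain dictionary is built from the batch labels of `scaled`; the
#' feature vocabulary is its column order. On return, the model carries the
#' per-epoch training log and the eval-mode latent coordinates (posterior
#' means) of the training cells.
#'
#' @param scaled a [ScaledCells-class] from the preprocessing recipes.
#' @param config a [modelConfig()]; `nFeatures`/`nDomains` are filled from
#'   the data if missing.
#' @param train a [trainConfig()].
#' @return a trained [CellBridgeModel-class].
#' @examples
#' \donttest{
#' sce <- simulateMultibatch(simSpec(nTypes = 2, nBatches = 2,
#'   cellsPerTypePerBatch = 40, nFeatures = 60, seed = 1))
#' sc <- preprocessRNA(sce, params = preprocessParams("rna",
#'   minGenesPerCell = 5, nTopFeatures = 50))
#' fit <- fitModel(sc, modelConfig(50, 2, hiddenDim = 64),
#'                 trainConfig(maxIterations = 50, seed = 1))
#' trainLog(fit)
#' }
#' @export
fitModel <- function(scaled, config = NULL, train = trainConfig()) {
  stopifnot(methods::is(scaled, "ScaledCells"),
            inherits(train, "trainConfig"))
  x <- scaledValues(scaled)
  batch <- batchLabels(scaled)
  if (is.null(config))
    config <- modelConfig(ncol(x), nlevels(batch))
  if (config$nFeatures != ncol(x))
    stop("config$nFeatures (", config$nFeatures,
         ") does not match data width (", ncol(x), ")")
  if (config$nDomains != nlevels(batch))
    stop("config$nDomains does not match the number of batches in the data")
  model <- .new_model(config, colnames(x), levels(batch), seed = train$seed)
  domainIdx <- as.integer(batch)
  n <- nrow(x)
  cfg <- config
  byBatch <- cfg$variant == "sample_by_batch_no_bn"
  plainAE <- cfg$variant == "plain_autoencoder"
  withEncBN <- cfg$variant != "sample_by_batch_no_bn"

  enc <- model@encoder
  dec <- model@decoder
  params <- function() list(W1 = enc$W1, b1 = enc$b1,
                            g1 = enc$bn$gamma, be1 = enc$bn$beta,
                            Wmu = enc$Wmu, bmu = enc$bmu,
                            Wlv = enc$Wlv, blv = enc$blv,
                            Wd = dec$W, bd = dec$b,
                            gd = dec$dsbn$gamma, bed = dec$dsbn$beta)
  adam <- lapply(params(), function(p)
    list(p = p, m = p * 0, v = p * 0))

  epochRows <- list()
  iter <- 0L
  epoch <- 0L
  best <- Inf
  bestState <- NULL
  wait <- 0L
  stopReason <- "max_iter"
  singleCellBatchSeen <- FALSE

  while (iter < train$maxIterations) {
    epoch <- epoch + 1L
    blocks <- sampleMinibatches(n, train$batchSize,
                                batch = batch, byBatch = byBatch)
    sums <- c(total = 0, reconstruction = 0, kl = 0)
    ncells <- 0L
    for (blk in blocks) {
      if (iter >= train$maxIterations) break
      iter <- iter + 1L
      m <- length(blk)
      if (m == 1L && !singleCellBatchSeen) {
        warning("mini-batch of a single cell encountered; ",
                "batch-norm variance degenerates to eps", call. = FALSE)
        singleCellBatchSeen <- TRUE
      }
      xb <- x[blk, , drop = FALSE]
      db <- domainIdx[blk]

      ## ---- forward ----
      fe <- encodeCells(xb, model, mode = "train", domainIdx = db)
      if (withEncBN) {
        enc$bn$mean <- fe$bn$runningMean
        enc$bn$var <- fe$bn$runningVar
      }
      eps <- if (plainAE) matrix(0, m, cfg$latentDim)
             else matrix(rnorm(m * cfg$latentDim), m, cfg$latentDim)
      z <- fe$mu + exp(fe$logvar / 2) * eps
      fd <- decodeCells(z, db, model, mode = "train")
      dec$dsbn <- fd$dsbn
      model@encoder <- enc
      model@decoder <- dec
      beta <- if (plainAE) 0 else cfg$beta
      loss <- elboLoss(fe$x[, seq_len(cfg$nFeatures), drop = FALSE],
                       fd$xhat, fe$mu, fe$logvar, beta)
      sums <- sums + unlist(loss) * m
      ncells <- ncells + m

      ## ---- backward ----
      xin <- fe$x                       # includes one-hot block if any
      xtar <- xin[, seq_len(cfg$nFeatures), drop = FALSE]
      dpre <- (fd$xhat - xtar) / m      # BCE+sigmoid, mean over cells
      # through DSBN (per-domain partitions)
      du <- matrix(0, m, cfg$nFeatures)
      dgd <- dec$dsbn$gamma * 0
      dbed <- dec$dsbn$beta * 0
      dIdx <- if (cfg$variant == "no_dsbn") rep(1L, m) else db
      for (d in sort(unique(dIdx))) {
        rows <- fd$caches[[d]]$rows
        bb <- .bn_backward(dpre[rows, , drop = FALSE], fd$caches[[d]],
                           dec$dsbn$gamma[d, ], cfg$bnEps)
        du[rows, ] <- bb$dx
        dgd[d, ] <- bb$dgamma
        dbed[d, ] <- bb$dbeta
      }
      dWd <- crossprod(z, du)
      dbd <- colSums(du)
      dz <- tcrossprod(du, dec$W)
      # split into mu / logvar paths (+ analytic KL gradients)
      dmu <- dz
      if (!plainAE) dmu <- dmu + beta * fe$mu / m
      dlv <- if (plainAE) matrix(0, m, cfg$latentDim) else
        dz * eps * 0.5 * exp(fe$logvar / 2) +
        beta * 0.5 * (exp(fe$logvar) - 1) / m
      da <- tcrossprod(dmu, enc$Wmu) + tcrossprod(dlv, enc$Wlv)
      dWmu <- crossprod(fe$a, dmu)
      dbmu <- colSums(dmu)
      dWlv <- crossprod(fe$a, dlv)
      dblv <- colSums(dlv)
      dy <- da * (fe$bn$y > 0)          # ReLU gate
      if (withEncBN) {
        bb <- .bn_backward(dy, fe$bn, enc$bn$gamma, cfg$bnEps)
        dh1 <- bb$dx
        dg1 <- bb$dgamma
        dbe1 <- bb$dbeta
      } else {
        dh1 <- da * (fe$h1 > 0)
        dg1 <- enc$bn$gamma * 0
        dbe1 <- enc$bn$beta * 0
      }
      dW1 <- crossprod(xin, dh1)
      db1 <- colSums(dh1)

      grads <- list(W1 = dW1, b1 = db1, g1 = dg1, be1 = dbe1,
                    Wmu = dWmu, bmu = dbmu, Wlv = dWlv, blv = dblv,
                    Wd = dWd, bd = dbd, gd = dgd, bed = dbed)
      for (nm in names(adam))
        adam[[nm]] <- .adam_step(adam[[nm]]$p, grads[[nm]], adam[[nm]],
                                 train$lr, train$betas, train$weightDecay,
                                 iter)
      enc$W1 <- adam$W1$p; enc$b1 <- adam$b1$p
      enc$bn$gamma <- adam$g1$p; enc$bn$beta <- adam$be1$p
      enc$Wmu <- adam$Wmu$p; enc$bmu <- adam$bmu$p
      enc$Wlv <- adam$Wlv$p; enc$blv <- adam$blv$p
      dec$W <- adam$Wd$p; dec$b <- adam$bd$p
      dec$dsbn$gamma <- adam$gd$p; dec$dsbn$beta <- adam$bed$p
      model@encoder <- enc
      model@decoder <- dec
    }

    epochLoss <- sums / ncells
    epochRows[[epoch]] <- data.frame(epoch = epoch, iterations = iter,
                                     total = epochLoss["total"],
                                     reconstruction =
                                       epochLoss["reconstruction"],
                                     kl = epochLoss["kl"])
    if (train$verbose)
      message(sprintf("epoch %d  iter %d  loss %.4f (recon %.4f, kl %.4f)",
                      epoch, iter, epochLoss["total"],
                      epochLoss["reconstruction"], epochLoss["kl"]))
    if (epochLoss["total"] < best - train$tol) {
      best <- epochLoss["total"]
      bestState <- list(enc = enc, dec = dec)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= train$patience) { stopReason <- "early_stop"; break }
    }
  }

  if (!is.null(bestState)) {
    model@encoder <- bestState$enc
    model@decoder <- bestState$dec
  }
  log <- do.call(rbind, epochRows)
  rownames(log) <- NULL
  attr(log, "stopReason") <- stopReason
  attr(log, "seed") <- train$seed
  model@trainLog <- log
  ev <- encodeCells(x, model, mode = "eval")
  lat <- ev$mu
  rownames(lat) <- rownames(x)
  model@latent <- lat
  methods::validObject(model)
  model
}
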