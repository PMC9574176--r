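#' Model configuration
#'
#' Architecture and objective settings for the integration model. The
#' network is deliberately small and fixed in shape: a batch-free encoder
#' (`nFeatures -> hiddenDim` linear, batch normalization, ReLU, then two
#' `hiddenDim -> latentDim` heads for the posterior mean and log-variance)
#' and a one-layer decoder (`latentDim -> nFeatures` linear, domain-specific
#' batch normalization, sigmoid). The loss is binary cross entropy (summed
#' over features, averaged over cells) plus `beta` times the KL divergence
#' of the posterior from a standard normal prior.
#'
#' Variants (for ablation):
#' * `"full"` -- the complete model;
#' * `"encoder_with_batch"` -- appends a one-hot domain block to the encoder
#'   input (breaks online projection; ablation only);
#' * `"no_dsbn"` -- decoder uses a single shared batch-norm layer;
#' * `"sample_by_batch_no_bn"` -- encoder batch-norm removed, and training
#'   mini-batches are drawn within single batches;
#' * `"plain_autoencoder"` -- no sampling (`z = mu`) and no KL term.
#'
#' @param nFeatures width of the input feature vocabulary.
#' @param nDomains number of training batches (domains).
#' @param latentDim latent dimensionality (default 10).
#' @param hiddenDim encoder hidden width (default 1024).
#' @param beta weight of the KL term (default 0.5).
#' @param variant model variant, see above.
#' @param bnEps numerical-stability constant in batch norm denominators.
#' @param bnMomentum exponential-moving-average rate for running statistics.
#' @return list of class `modelConfig`.
#' @export
modelConfig <- function(nFeatures, nDomains, latentDim = 10L,
                        hiddenDim = 1024L, beta = 0.5,
                        variant = c("full", "encoder_with_batch", "no_dsbn",
                                    "sample_by_batch_no_bn",
                                    "plain_autoencoder"),
                        bnEps = 1e-5, bnMomentum = 0.1) {
  variant <- match.arg(variant)
  stopifnot(nFeatures >= 1, nDomains >= 1, latentDim >= 1, hiddenDim >= 1,
            beta >= 0, bnEps > 0, bnMomentum > 0, bnMomentum < 1)
  structure(list(nFeatures = as.integer(nFeatures),
                 nDomains = as.integer(nDomains),
                 latentDim = as.integer(latentDim),
                 hiddenDim = as.integer(hiddenDim),
                 beta = beta, variant = variant,
                 bnEps = bnEps, bnMomentum = bnMomentum),
            class = "modelConfig")
}

# Kaiming-uniform fan-in initialization; gain sqrt(2) before ReLU layers,
# 1 for linear outputs. Biases start at zero, BN affines at gamma=1/beta=0.
.init_linear <- function(nIn, nOut, gain = 1) {
  bound <- gain * sqrt(3 / nIn)
  matrix(runif(nIn * nOut, -bound, bound), nIn, nOut)
}

.init_bn <- function(n) list(gamma = rep(1, n), beta = rep(0, n),
                             mean = rep(0, n), var = rep(1, n))

# Construct an untrained model. Domain/feature dictionaries fix the column
# order the model will forever expect.
.new_model <- function(config, features, domains, seed = 0L) {
  set.seed(seed)
  nIn <- config$nFeatures +
    if (config$variant == "encoder_with_batch") config$nDomains else 0L
  enc <- list(
    W1 = .init_linear(nIn, config$hiddenDim, gain = sqrt(2)),
    b1 = rep(0, config$hiddenDim),
    bn = .init_bn(config$hiddenDim),
    Wmu = .init_linear(config$hiddenDim, config$latentDim),
    bmu = rep(0, config$latentDim),
    Wlv = .init_linear(config$hiddenDim, config$latentDim),
    blv = rep(0, config$latentDim)
  )
  nd <- if (config$variant == "no_dsbn") 1L else config$nDomains
  dec <- list(
    W = .init_linear(config$latentDim, config$nFeatures),
    b = rep(0, config$nFeatures),
    dsbn = list(gamma = matrix(1, nd, config$nFeatures),
                beta = matrix(0, nd, config$nFeatures),
                mean = matrix(0, nd, config$nFeatures),
                var = matrix(1, nd, config$nFeatures))
  )
  methods::new("CellBridgeModel", config = unclass(config), encoder = enc,
               decoder = dec, domains = as.character(domains),
               features = as.character(features),
               trainLog = data.frame(), latent = matrix(0, 0, config$latentDim),
               version = "cellbridge-model-1")
}

#' Batch normalization forward pass
#'
#' Whitens each feature within a mini-batch and applies a learned affine
#' map. In `"train"` mode the mini-batch mean and (biased) variance are
#' used, and the running statistics are updated by an exponential moving
#' average with rate `momentum`; in `"eval"` mode the running statistics
#' are used instead, so the map is deterministic per row and independent of
#' co-batched rows. A train-mode mini-batch of one row is permitted (its
#' batch variance is zero; `eps` keeps the map finite).
#'
#' @param h numeric matrix, rows = samples, columns = features.
#' @param gamma,beta per-feature affine parameters.
#' @param mode `"train"` or `"eval"`.
#' @param runningMean,runningVar per-feature running statistics.
#' @param eps variance-stabilizing constant.
#' @param momentum running-statistics update rate in (0, 1).
#' @return list: `y` (normalized output), updated `runningMean` and
#'   `runningVar`, and (train mode) the mini-batch `batchMean`/`batchVar`.
#' @export
batchNormForward <- function(h, gamma, beta, mode = c("train", "eval"),
                             runningMean = rep(0, ncol(h)),
                             runningVar = rep(1, ncol(h)),
                             eps = 1e-5, momentum = 0.1) {
  mode <- match.arg(mode)
  h <- as.matrix(h)
  if (mode == "train") {
    m <- nrow(h)
    mu <- colMeans(h)
    v <- colMeans(h^2) - mu^2
    v <- pmax(v, 0)                    # guard tiny negative rounding
    xhat <- sweep(sweep(h, 2, mu), 2, sqrt(v + eps), "/")
    runningMean <- (1 - momentum) * runningMean + momentum * mu
    runningVar <- (1 - momentum) * runningVar + momentum * v
    y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
    list(y = y, runningMean = runningMean, runningVar = runningVar,
         batchMean = mu, batchVar = v, xhat = xhat)
  } else {
    xhat <- sweep(sweep(h, 2, runningMean), 2, sqrt(runningVar + eps), "/")
    y <- sweep(sweep(xhat, 2, gamma, "*"), 2, beta, "+")
    list(y = y, runningMean = runningMean, runningVar = runningVar)
  }
}

#' Domain-specific batch normalization forward pass
#'
#' Partitions the rows of `h` by their domain (training batch) label and
#' passes each partition through its own batch-normalization branch with
#' that domain's affine parameters and running statistics; outputs are
#' reassembled in the input row order. With one domain this reduces exactly
#' to [batchNormForward()].
#'
#' @param h numeric matrix, rows = samples.
#' @param domainIdx integer vector of 1-based domain indices per row.
#' @param dsbn list with matrices `gamma`, `beta`, `mean`, `var`
#'   (domains x features).
#' @param mode `"train"` or `"eval"`.
#' @param eps,momentum as in [batchNormForward()].
#' @return list: `y`, updated `dsbn`, and per-domain caches (train mode).
#' @export
dsbnForward <- function(h, domainIdx, dsbn, mode = c("train", "eval"),
                        eps = 1e-5, momentum = 0.1) {
  mode <- match.arg(mode)
  nd <- nrow(dsbn$gamma)
  if (any(domainIdx < 1 | domainIdx > nd))
    stop("unknown domain index; the decoder only accepts domains seen in ",
         "training")
  y <- matrix(0, nrow(h), ncol(h))
  caches <- vector("list", nd)
  for (d in sort(unique(domainIdx))) {
    rows <- which(domainIdx == d)
    out <- batchNormForward(h[rows, , drop = FALSE],
                            dsbn$gamma[d, ], dsbn$beta[d, ], mode,
                            dsbn$mean[d, ], dsbn$var[d, ], eps, momentum)
    y[rows, ] <- out$y
    dsbn$mean[d, ] <- out$runningMean
    dsbn$var[d, ] <- out$runningVar
    caches[[d]] <- c(out[setdiff(names(out), "y")], list(rows = rows))
  }
  list(y = y, dsbn = dsbn, caches = caches)
}

#' Encode cells into the latent space
#'
#' Runs the batch-free encoder: linear map to the hidden layer, batch
#' normalization, ReLU, then the mean and log-variance heads. In `"eval"`
#' mode batch normalization uses the stored running statistics, so each
#' cell's output is a pure function of its own input -- the property that
#' makes frozen-encoder projection of new batches well defined.
#'
#' @param x numeric matrix of scaled values (cells x features, in \[0, 1\]),
#'   or a [ScaledCells-class].
#' @param model a [CellBridgeModel-class].
#' @param mode `"train"` or `"eval"` (default).
#' @param domainIdx 1-based domain indices, required only by the
#'   `encoder_with_batch` ablation variant.
#' @return list: `mu` and `logvar` matrices (cells x latent dims). In train
#'   mode also the updated encoder state and backward caches.
#' @export
encodeCells <- function(x, model, mode = c("eval", "train"),
                        domainIdx = NULL) {
  mode <- match.arg(mode)
  if (methods::is(x, "ScaledCells")) x <- scaledValues(x)
  x <- as.matrix(x)
  cfg <- model@config
  enc <- model@encoder
  if (cfg$variant == "encoder_with_batch") {
    if (is.null(domainIdx))
      stop("variant 'encoder_with_batch' needs domain indices at encode time")
    onehot <- matrix(0, nrow(x), cfg$nDomains)
    onehot[cbind(seq_len(nrow(x)), domainIdx)] <- 1
    x <- cbind(x, onehot)
  }
  if (ncol(x) != nrow(enc$W1))
    stop("input width ", ncol(x), " does not match model input width ",
         nrow(enc$W1))
  h1 <- x %*% enc$W1 + matrix(enc$b1, nrow(x), cfg$hiddenDim, byrow = TRUE)
  if (cfg$variant == "sample_by_batch_no_bn") {
    bnout <- list(y = h1)
  } else {
    bnout <- batchNormForward(h1, enc$bn$gamma, enc$bn$beta, mode,
                              enc$bn$mean, enc$bn$var, cfg$bnEps,
                              cfg$bnMomentum)
  }
  a <- pmax(bnout$y, 0)
  mu <- a %*% enc$Wmu + matrix(enc$bmu, nrow(x), cfg$latentDim, byrow = TRUE)
  lv <- a %*% enc$Wlv + matrix(enc$blv, nrow(x), cfg$latentDim, byrow = TRUE)
  lv <- pmin(pmax(lv, -15), 15)        # keep exp(logvar) finite
  out <- list(mu = mu, logvar = lv)
  if (mode == "train")
    out <- c(out, list(x = x, h1 = h1, bn = bnout, a = a))
  out
}

#' Reparameterization: sample latent representations
#'
#' `z = mu + exp(logvar / 2) * eps` with `eps` standard-normal, so the
#' sampling step is differentiable in `mu` and `logvar`.
#'
#' @param mu,logvar matrices from [encodeCells()].
#' @param eps standard-normal draws of the same shape (drawn internally if
#'   omitted).
#' @return matrix `z` of the same shape as `mu`.
#' @export
reparameterize <- function(mu, logvar, eps = NULL) {
  stopifnot(identical(dim(mu), dim(logvar)))
  if (is.null(eps)) eps <- matrix(rnorm(length(mu)), nrow(mu), ncol(mu))
  stopifnot(identical(dim(eps), dim(mu)))
  mu + exp(logvar / 2) * eps
}

#' Decode latent representations back to feature space
#'
#' One linear layer from the latent space to feature space, then
#' domain-specific batch normalization indexed by each cell's training
#' batch, then a sigmoid -- reconstructing the \[0, 1\]-scaled profile with
#' its batch-specific variation restored. Projection of new data never
#' calls the decoder, which is why unseen batches need no domain
#' registration.
#'
#' @param z latent matrix (cells x latent dims).
#' @param domainIdx 1-based training-domain index per cell (ignored by the
#'   `no_dsbn` variant, which uses one shared branch).
#' @param model a [CellBridgeModel-class].
#' @param mode `"train"` or `"eval"`.
#' @return list: `xhat` (cells x features, in (0, 1)), plus updated decoder
#'   state and caches in train mode.
#' @export
decodeCells <- function(z, domainIdx, model, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  cfg <- model@config
  dec <- model@decoder
  if (ncol(z) != cfg$latentDim)
    stop("latent width mismatch: got ", ncol(z), ", expected ", cfg$latentDim)
  if (cfg$variant == "no_dsbn") domainIdx <- rep(1L, nrow(z))
  u <- z %*% dec$W + matrix(dec$b, nrow(z), cfg$nFeatures, byrow = TRUE)
  ds <- dsbnForward(u, domainIdx, dec$dsbn, mode, cfg$bnEps, cfg$bnMomentum)
  xhat <- 1 / (1 + exp(-ds$y))
  out <- list(xhat = xhat, dsbn = ds$dsbn)
  if (mode == "train") out <- c(out, list(u = u, caches = ds$caches))
  out
}

#' Training objective: reconstruction + weighted KL
#'
#' Reconstruction is the binary cross entropy between the decoded profile
#' and the input, summed over features and averaged over cells (predictions
#' are clamped away from 0/1 by `clampEps` before taking logs). The
#' regularizer is the KL divergence of the diagonal-Gaussian posterior from
#' the standard-normal prior, `0.5 * sum(mu^2 + sigma^2 - 1 - log sigma^2)`
#' per cell, averaged over cells. The total is
#' `reconstruction + beta * kl`.
#'
#' @param x input matrix in \[0, 1\] (cells x features).
#' @param xhat decoded matrix in (0, 1), same shape.
#' @param mu,logvar posterior parameters (cells x latent dims).
#' @param beta KL weight.
#' @param clampEps clamp for the BCE logarithms.
#' @return list with components `total`, `reconstruction`, `kl`.
#' @export
elboLoss <- function(x, xhat, mu, logvar, beta = 0.5, clampEps = 1e-8) {
  stopifnot(identical(dim(x), dim(xhat)), identical(dim(mu), dim(logvar)))
  n <- nrow(x)
  p <- pmin(pmax(xhat, clampEps), 1 - clampEps)
  recon <- -sum(x * log(p) + (1 - x) * log(1 - p)) / n
  kl <- 0.5 * sum(mu^2 + exp(logvar) - 1 - logvar) / n
  total <- recon + beta * kl
  if (!is.finite(total)) stop("non-finite loss")
  list(total = total, reconstruction = recon, kl = kl)
}

#' Count model parameters
#'
#' Closed-form audit of the architecture: learnable weights (linear maps,
#' biases, batch-norm affine parameters on both the encoder and the
#' per-domain decoder branches) and non-learnable running statistics are
#' reported separately.
#'
#' @param model a [CellBridgeModel-class].
#' @return list: `learnable`, `running`, `total` (integers).
#' @export
parameterCount <- function(model) {
  enc <- model@encoder
  dec <- model@decoder
  learnable <- length(enc$W1) + length(enc$b1) +
    length(enc$bn$gamma) + length(enc$bn$beta) +
    length(enc$Wmu) + length(enc$bmu) + length(enc$Wlv) + length(enc$blv) +
    length(dec$W) + length(dec$b) +
    length(dec$dsbn$gamma) + length(dec$dsbn$beta)
  running <- length(enc$bn$mean) + length(enc$bn$var) +
    length(dec$dsbn$mean) + length(dec$dsbn$var)
  list(learnable = learnable, running = running,
       total = learnable + running)
}
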