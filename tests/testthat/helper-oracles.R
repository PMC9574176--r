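# Independent reference implementations used to check the package's
# operations. These are deliberately written as slow, literal scalar loops
# so they share no code path with the implementation under test.

# --- network oracles -----------------------------------------------------

# affine -> BN(running stats) -> ReLU -> two affine heads, one cell at a
# time, scalar loops only.
oracle_encode_eval <- function(x, enc, eps) {
  nH <- length(enc$b1)
  nL <- length(enc$bmu)
  out_mu <- matrix(0, nrow(x), nL)
  out_lv <- matrix(0, nrow(x), nL)
  for (r in seq_len(nrow(x))) {
    h <- numeric(nH)
    for (j in seq_len(nH)) {
      s <- enc$b1[j]
      for (i in seq_len(ncol(x))) s <- s + x[r, i] * enc$W1[i, j]
      hn <- (s - enc$bn$mean[j]) / sqrt(enc$bn$var[j] + eps)
      a <- enc$bn$gamma[j] * hn + enc$bn$beta[j]
      h[j] <- max(a, 0)
    }
    for (l in seq_len(nL)) {
      smu <- enc$bmu[l]; slv <- enc$blv[l]
      for (j in seq_len(nH)) {
        smu <- smu + h[j] * enc$Wmu[j, l]
        slv <- slv + h[j] * enc$Wlv[j, l]
      }
      out_mu[r, l] <- smu
      out_lv[r, l] <- min(max(slv, -15), 15)
    }
  }
  list(mu = out_mu, logvar = out_lv)
}

# affine -> per-domain BN(running) -> sigmoid, scalar loops.
oracle_decode_eval <- function(z, domainIdx, dec, eps) {
  nF <- length(dec$b)
  out <- matrix(0, nrow(z), nF)
  for (r in seq_len(nrow(z))) {
    d <- domainIdx[r]
    for (j in seq_len(nF)) {
      s <- dec$b[j]
      for (l in seq_len(ncol(z))) s <- s + z[r, l] * dec$W[l, j]
      hn <- (s - dec$dsbn$mean[d, j]) / sqrt(dec$dsbn$var[d, j] + eps)
      y <- dec$dsbn$gamma[d, j] * hn + dec$dsbn$beta[d, j]
      out[r, j] <- 1 / (1 + exp(-y))
    }
  }
  out
}

# --- metric oracles ------------------------------------------------------

# ARI by explicit pair counting over all C(n,2) item pairs.
oracle_ari <- function(a, b) {
  n <- length(a)
  s11 <- s00 <- s10 <- s01 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (!sa && !sb) s00 <- s00 + 1
    else if (sa) s10 <- s10 + 1
    else s01 <- s01 + 1
  }
  np <- n * (n - 1) / 2
  expected <- (s11 + s10) * (s11 + s01) / np
  maxidx <- ((s11 + s10) + (s11 + s01)) / 2
  if (maxidx == expected) return(1)
  (s11 - expected) / (maxidx - expected)
}

# NMI from explicit joint/marginal frequencies.
oracle_nmi <- function(a, b) {
  n <- length(a)
  ua <- unique(a); ub <- unique(b)
  ha <- 0
  for (x in ua) { p <- sum(a == x) / n; ha <- ha - p * log(p) }
  hb <- 0
  for (y in ub) { p <- sum(b == y) / n; hb <- hb - p * log(p) }
  if (ha == 0 || hb == 0) return(0)
  mi <- 0
  for (x in ua) for (y in ub) {
    pxy <- sum(a == x & b == y) / n
    if (pxy > 0) mi <- mi + pxy * log(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
  }
  min(max(mi, 0) / sqrt(ha * hb), 1)
}

oracle_f1_macro <- function(truth, pred) {
  classes <- sort(unique(c(truth, pred)))
  f1s <- numeric(0)
  for (cl in classes) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    f1s <- c(f1s, if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn))
  }
  mean(f1s)
}

oracle_confusion <- function(truth, pred) {
  ut <- sort(unique(truth)); up <- sort(unique(c(pred, truth)))
  C <- matrix(0, length(ut), length(up), dimnames = list(ut, up))
  for (i in seq_along(ut)) {
    sel <- truth == ut[i]
    for (j in seq_along(up)) C[i, j] <- 100 * sum(pred[sel] == up[j]) / sum(sel)
  }
  C
}

# over-correction by O(n^2) distance scans with deterministic ordering.
oracle_over_correction <- function(coords, labels, k) {
  n <- nrow(coords)
  agree <- 0
  for (i in seq_len(n)) {
    d <- sqrt(rowSums((coords - matrix(coords[i, ], n, ncol(coords),
                                       byrow = TRUE))^2))
    d[i] <- Inf
    nb <- order(d)[seq_len(k)]
    agree <- agree + sum(labels[nb] == labels[i])
  }
  1 - agree / (n * k)
}

# LISI with an independently coded bandwidth bisection over ALL other
# cells (no neighbour truncation), for small n.
oracle_lisi <- function(coords, labels, perplexity = 30) {
  n <- nrow(coords)
  vals <- numeric(n)
  k <- min(n - 1, 3 * perplexity)
  perp <- min(perplexity, k - 1)
  for (i in seq_len(n)) {
    d2 <- rowSums((coords - matrix(coords[i, ], n, ncol(coords),
                                   byrow = TRUE))^2)
    ord <- order(d2)
    ord <- ord[ord != i][seq_len(k)]
    di <- d2[ord]
    lo <- 0; hi <- Inf; beta <- 1
    for (it in 1:60) {
      w <- exp(-beta * di)
      p <- w / sum(w)
      h <- -sum(p[p > 0] * log(p[p > 0]))
      if (abs(h - log(perp)) < 1e-7) break
      if (h > log(perp)) { lo <- beta
        beta <- if (is.finite(hi)) (beta + hi) / 2 else 2 * beta
      } else { hi <- beta; beta <- (lo + beta) / 2 }
    }
    ps <- tapply(p, factor(labels[ord], levels = unique(labels)), sum)
    ps[is.na(ps)] <- 0
    vals[i] <- 1 / sum(ps^2)
  }
  vals
}

# all label vectors of length n over an alphabet, as a character matrix
enumerate_labelings <- function(n, alphabet) {
  g <- do.call(expand.grid, c(rep(list(alphabet), n),
                              stringsAsFactors = FALSE))
  as.matrix(g)
}

# --- shared small fixtures ----------------------------------------------

small_scaled <- function(seed = 1, nTypes = 2, nBatches = 2, cells = 30,
                         nFeatures = 60, nTop = 50) {
  sce <- simulateMultibatch(simSpec(nTypes = nTypes, nBatches = nBatches,
                                    cellsPerTypePerBatch = cells,
                                    nFeatures = nFeatures, seed = seed))
  preprocessRNA(sce, params = preprocessParams("rna", minGenesPerCell = 5,
                                               nTopFeatures = nTop))
}

# a tiny trained model + its data, memoised across tests in one session
.tiny_cache <- new.env(parent = emptyenv())
tiny_fit <- function() {
  if (is.null(.tiny_cache$fit)) {
    sc <- small_scaled(seed = 3, nTypes = 3, nBatches = 2, cells = 40,
                       nFeatures = 80, nTop = 60)
    fit <- fitModel(sc, modelConfig(ncol(scaledValues(sc)), 2,
                                    hiddenDim = 64),
                    trainConfig(seed = 3, maxIterations = 600))
    .tiny_cache$sc <- sc
    .tiny_cache$fit <- fit
  }
  list(sc = .tiny_cache$sc, fit = .tiny_cache$fit)
}
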