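test_that("ARI and NMI agree with brute-force oracles on small cases", {
  expect_equal(adjustedRandIndex(c(1, 1, 2, 2, 3, 3), c(1, 1, 2, 2, 3, 3)), 1)
  expect_equal(adjustedRandIndex(rep("x", 5), letters[1:5]), 0)
  expect_equal(normalizedMutualInfo(letters[c(1, 1, 2, 2)],
                                    letters[c(1, 1, 2, 2)]), 1)
  # independent labels on a balanced 2x2 design
  expect_equal(normalizedMutualInfo(c("A", "A", "B", "B"),
                                    c("x", "y", "x", "y")), 0)
  # {AABB} vs {ABAB} against direct evaluation
  a <- c("A", "A", "B", "B"); b <- c("A", "B", "A", "B")
  expect_equal(adjustedRandIndex(a, b), oracle_ari(a, b), tolerance = 1e-12)
  expect_equal(normalizedMutualInfo(a, b), oracle_nmi(a, b),
               tolerance = 1e-12)
})

test_that("ARI/NMI/F1 match oracles on exhaustive and random label pairs", {
  # exhaustive over all pairs of 3-letter labelings at small n (the
  # acceptance suite extends this to longer vectors)
  for (n in 2:3) {
    labs <- enumerate_labelings(n, c("a", "b", "c"))
    for (i in seq_len(nrow(labs))) for (j in seq_len(nrow(labs))) {
      a <- labs[i, ]; b <- labs[j, ]
      expect_equal(adjustedRandIndex(a, b), oracle_ari(a, b),
                   tolerance = 1e-10)
      expect_equal(suppressWarnings(normalizedMutualInfo(a, b)),
                   suppressWarnings(oracle_nmi(a, b)), tolerance = 1e-10)
      expect_equal(f1Macro(a, b), oracle_f1_macro(a, b), tolerance = 1e-10)
    }
  }
  # random subsample at lengths 5..8, plus larger seeded cases
  set.seed(31)
  for (n in 5:8) {
    for (r in 1:100) {
      a <- sample(c("a", "b", "c"), n, replace = TRUE)
      b <- sample(c("a", "b", "c"), n, replace = TRUE)
      expect_equal(adjustedRandIndex(a, b), oracle_ari(a, b),
                   tolerance = 1e-10)
      expect_equal(suppressWarnings(normalizedMutualInfo(a, b)),
                   suppressWarnings(oracle_nmi(a, b)), tolerance = 1e-10)
      expect_equal(f1Macro(a, b), oracle_f1_macro(a, b), tolerance = 1e-10)
    }
  }
  for (r in 1:25) {
    a <- sample(letters[1:5], 200, replace = TRUE)
    b <- sample(letters[1:5], 200, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), oracle_ari(a, b),
                 tolerance = 1e-10)
    expect_equal(normalizedMutualInfo(a, b), oracle_nmi(a, b),
                 tolerance = 1e-10)
    expect_equal(f1Macro(a, b), oracle_f1_macro(a, b), tolerance = 1e-10)
  }
})

test_that("ARI cross-checks against an established implementation", {
  skip_if_not_installed("mclust")
  set.seed(32)
  for (r in 1:20) {
    a <- sample(letters[1:4], 100, replace = TRUE)
    b <- sample(letters[1:4], 100, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-10)
  }
})

test_that("ARI/NMI are symmetric and invariant to label renaming", {
  set.seed(33)
  for (r in 1:20) {
    a <- sample(letters[1:3], 40, replace = TRUE)
    b <- sample(letters[1:4], 40, replace = TRUE)
    expect_equal(adjustedRandIndex(a, b), adjustedRandIndex(b, a))
    expect_equal(normalizedMutualInfo(a, b), normalizedMutualInfo(b, a))
    ren <- setNames(sample(LETTERS[1:4]), letters[1:4])
    expect_equal(adjustedRandIndex(a, b), adjustedRandIndex(a, ren[b]))
    expect_equal(normalizedMutualInfo(a, b), normalizedMutualInfo(a, ren[b]))
  }
})

test_that("the silhouette matches hand computations and guards", {
  # two tight pairs far apart on a line
  coords <- matrix(c(0, 0.1, 10, 10.1), 4, 1)
  labs <- c("u", "u", "v", "v")
  # per-point a = 0.1; b in {9.95, 10.05}; s = (b - a)/b
  want <- mean(c((9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05,
                 (9.95 - 0.1) / 9.95, (10.05 - 0.1) / 10.05))
  expect_equal(silhouetteOnEmbedding(coords, labs), want, tolerance = 1e-12)

  skip_if_not_installed("cluster")
  set.seed(34)
  c2 <- matrix(rnorm(120), 60, 2)
  l2 <- sample(c("p", "q", "r"), 60, replace = TRUE)
  sil <- cluster::silhouette(as.integer(factor(l2)), dist(c2))
  expect_equal(silhouetteOnEmbedding(c2, l2), mean(sil[, 3]),
               tolerance = 1e-10)

  # two interleaved identical clusters score near zero or below
  c3 <- rbind(matrix(rnorm(100), 50, 2), matrix(rnorm(100), 50, 2))
  l3 <- rep(c("a", "b"), each = 50)
  expect_lt(silhouetteOnEmbedding(c3, l3), 0.1)
  # all points identical: 0/0 guarded to 0
  expect_equal(silhouetteOnEmbedding(matrix(1, 10, 2),
                                     rep(c("a", "b"), 5)), 0)
})

test_that("batch entropy mixing attains its analytic extremes", {
  # alternating batches on a circle at even k: every 28-neighbourhood is
  # exactly 14/14 (offset parity), forcing E = ln(1/2), rescaled 1
  n <- 200
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring <- cbind(cos(th), sin(th))
  batch <- rep(c("b1", "b2"), n / 2)
  out <- batchEntropyMixing(ring, batch, nNeighbors = 28, seed = 1)
  expect_equal(out$raw, log(0.5), tolerance = 1e-6)
  expect_equal(out$rescaled, 1, tolerance = 1e-6)

  # fully separated batches: every neighbourhood is pure, E = 0
  sep <- rbind(matrix(rnorm(120, 0), 60, 2), matrix(rnorm(120, 100), 60, 2))
  bsep <- rep(c("b1", "b2"), each = 60)
  out2 <- batchEntropyMixing(sep, bsep, seed = 1)
  expect_equal(out2$raw, 0, tolerance = 1e-12)
  expect_equal(out2$rescaled, 0, tolerance = 1e-12)
})

test_that("the p/P correction removes batch-size imbalance", {
  # a well-mixed but 90/10 unbalanced pool: the corrected entropy should
  # still approach perfect mixing
  set.seed(35)
  n <- 2000
  coords <- matrix(rnorm(2 * n), n, 2)
  batch <- sample(rep(c("big", "small"), c(0.9 * n, 0.1 * n)))
  out <- batchEntropyMixing(coords, batch, nProbes = 300, nIterations = 3,
                            seed = 2)
  expect_gt(out$rescaled, 0.8)
})

test_that("the common-type mask restricts scoring and guards batches", {
  set.seed(36)
  coords <- matrix(rnorm(400), 200, 2)
  batch <- rep(c("b1", "b2"), each = 100)
  type <- c(rep("shared", 60), rep("only1", 40),
            rep("shared", 60), rep("only2", 40))
  out <- batchEntropyMixing(coords, batch, cellType = type, seed = 1)
  expect_true(out$rescaled >= 0 && out$rescaled <= 1)
  expect_error(batchEntropyMixing(coords, rep("b1", 200), seed = 1),
               "fewer than 2 batches")
})

test_that("LISI attains its analytic extremes and matches its oracle", {
  set.seed(37)
  coords <- matrix(rnorm(160), 80, 2)
  one <- lisiScore(coords, rep("only", 80))
  expect_true(all(one$perCell == 1))

  # a probe at the centre of an equidistant 45/45 circle sees an exactly
  # uniform kernel over two labels: its iLISI is exactly 2; on an
  # alternating ring every cell is close to (but not exactly at) 2
  th90 <- 2 * pi * (seq_len(90) - 1) / 90
  star <- rbind(c(0, 0), cbind(cos(th90), sin(th90)))
  expect_equal(lisiScore(star, c("a", rep(c("a", "b"), 45)))$perCell[1], 2,
               tolerance = 1e-6)
  n <- 120
  th <- 2 * pi * (seq_len(n) - 1) / n
  ring <- cbind(cos(th), sin(th))
  out <- lisiScore(ring, rep(c("a", "b"), n / 2))
  expect_equal(out$perCell, rep(2, n), tolerance = 0.02)

  # independent implementation on a small seeded mixture
  c2 <- matrix(rnorm(100), 50, 2)
  l2 <- sample(c("a", "b"), 50, replace = TRUE)
  got <- lisiScore(c2, l2, perplexity = 10)
  want <- oracle_lisi(c2, l2, perplexity = 10)
  expect_equal(got$perCell, want, tolerance = 1e-5)

  # range invariant
  set.seed(38)
  c3 <- matrix(rnorm(300), 150, 2)
  l3 <- sample(c("a", "b", "c"), 150, replace = TRUE)
  v <- lisiScore(c3, l3)$perCell
  expect_true(all(v >= 1 - 1e-9 & v <= 3 + 1e-9))
})

test_that("the over-correction score counts inconsistent neighbourhoods", {
  set.seed(39)
  # two far-separated pure blobs: no inconsistent neighbours
  blobs <- rbind(matrix(rnorm(60), 30, 2), matrix(rnorm(60, 50), 30, 2))
  labs <- rep(c("a", "b"), each = 30)
  expect_equal(overCorrectionScore(blobs, labs, k = 5), 0)

  # alternating labels along a line with k = 1: every nearest neighbour
  # differs, the score attains 1
  line <- matrix(seq_len(20), 20, 1)
  expect_equal(overCorrectionScore(line, rep(c("a", "b"), 10), k = 1), 1)

  # random labels over one blob approach 0.5 for two balanced types
  pool <- matrix(rnorm(400), 200, 2)
  rnd <- sample(rep(c("a", "b"), each = 100))
  expect_lt(abs(overCorrectionScore(pool, rnd, k = 60) - 0.5), 0.06)

  # brute-force oracle + the complement identity
  c4 <- matrix(rnorm(80), 40, 2)
  l4 <- sample(c("a", "b", "c"), 40, replace = TRUE)
  expect_equal(overCorrectionScore(c4, l4, k = 7),
               oracle_over_correction(c4, l4, 7), tolerance = 1e-12)
  expect_error(overCorrectionScore(c4, l4, k = 40), "smaller")
})

test_that("macro F1 follows the per-class formula", {
  expect_equal(f1Macro(c("a", "b"), c("a", "b")), 1)
  # symmetric binary confusion with TP=1, FP=1, FN=1 per class
  expect_equal(f1Macro(c("a", "a", "b", "b"), c("a", "b", "a", "b")), 0.5)
  set.seed(40)
  tl <- sample(c("x", "y", "z"), 90, replace = TRUE)
  pl <- sample(c("x", "y", "z"), 90, replace = TRUE)
  expect_equal(f1Macro(tl, pl), oracle_f1_macro(tl, pl), tolerance = 1e-12)
})

test_that("stochastic metrics are reproducible and monotone in mixing", {
  set.seed(41)
  coords <- matrix(rnorm(600), 300, 2)
  batch <- sample(c("b1", "b2"), 300, replace = TRUE)
  a <- batchEntropyMixing(coords, batch, seed = 7)
  b <- batchEntropyMixing(coords, batch, seed = 7)
  expect_identical(a, b)

  # slide two separated batches onto each other: mixing increases
  sep <- rbind(matrix(rnorm(300, 0), 150, 2), matrix(rnorm(300, 40), 150, 2))
  bb <- rep(c("b1", "b2"), each = 150)
  prev <- -Inf
  for (alpha in seq(0, 1, length.out = 5)) {
    mix <- sep
    mix[151:300, 1] <- sep[151:300, 1] - alpha * 40
    s <- batchEntropyMixing(mix, bb, seed = 3)$rescaled
    expect_gte(s, prev - 1e-9)
    prev <- s
  }
})
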