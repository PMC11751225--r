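# Architecture forward pass: soft thresholding, attention thresholds,
# feature extractor, residual unit, parameter accounting.

test_that("soft thresholding follows the three-branch definition", {
  expect_equal(softThreshold(2.0, 0.5), 1.5)
  expect_equal(softThreshold(0.3, 0.5), 0.0)
  expect_equal(softThreshold(-2.0, 0.5), -1.5)
  x <- rnorm(100)
  expect_identical(softThreshold(x, 0), x)
  # per-channel thresholds broadcast over rows
  m <- rbind(c(2, -2), c(2, -2))
  expect_equal(softThreshold(m, c(0.5, 1.5)), rbind(c(1.5, -1.5), c(0.5, -0.5)))
  expect_error(softThreshold(x, -0.1), "invalid threshold")
})

test_that("attention thresholds: sigma = 1/2 at zero parameters, tau = sigma * mean|U|", {
  cfg <- smallCfg()
  p <- zeroParams(cfg)
  U <- matrix(rep(c(2, -2), 2 * cfg$nFilters), nrow = cfg$nFilters,
              ncol = 4, byrow = TRUE)
  st <- seThresholds(U, p, "CW")
  expect_equal(st$sigma, rep(0.5, cfg$nFilters))
  expect_equal(st$tau, rep(1.0, cfg$nFilters))
  # zero feature map -> zero threshold regardless of sigma
  st0 <- seThresholds(matrix(0, cfg$nFilters, 4), p, "CW")
  expect_equal(st0$tau, rep(0, cfg$nFilters))
  expect_error(seThresholds(matrix(c(1, NA), 2, 2), p, "CW"), "non-finite")
})

test_that("thresholds respect 0 <= tau <= mean|U| and match direct recomputation", {
  cfg <- smallCfg()
  for (i in 1:1000) {
    p <- initParams(cfg, seed = i)
    U <- matrix(rnorm(cfg$nFilters * 12, sd = runif(1, 0.1, 3)),
                cfg$nFilters, 12)
    st <- seThresholds(U, p, "CW")
    a <- rowMeans(abs(U))
    # direct recomputation: dense-reduce, normalize+rectify, dense-restore
    z <- as.vector(a %*% p$se1_w) + p$se1_b
    z <- (z - p$sebn_rm) / sqrt(p$sebn_rv + 1e-5) * p$sebn_g + p$sebn_b
    z <- pmax(z, 0)
    z <- as.vector(z %*% p$se2_w) + p$se2_b
    sig <- 1 / (1 + exp(-z))
    expect_equal(st$sigma, sig, tolerance = 1e-12)
    expect_equal(st$tau, sig * a, tolerance = 1e-12)
    expect_true(all(st$tau >= 0 & st$tau <= a + 1e-12))
    expect_true(all(st$sigma > 0 & st$sigma < 1))
  }
})

test_that("channel-shared mode yields one threshold bounded by the grand mean", {
  cfg <- smallCfg(thresholdMode = "CS")
  p <- initParams(cfg, seed = 2)
  U <- matrix(rnorm(cfg$nFilters * 20), cfg$nFilters)
  st <- seThresholds(U, p, "CS")
  expect_length(st$tau, 1)
  expect_true(st$tau >= 0 && st$tau <= mean(abs(U)))
})

test_that("feature extractor geometry and the zero/constant-input oracles", {
  cfg <- modelConfig()
  p <- initParams(cfg, seed = 1)
  I <- baseFeForward(rnorm(384), cfg, p)
  expect_equal(dim(I), c(32L, 192L))
  expect_error(baseFeForward(rnorm(100), cfg, p), "length")

  # all-zero epoch, zero conv bias and BN shift -> all-zero output
  p0 <- p
  p0$conv_b[] <- 0
  p0$bn1_b[] <- 0
  expect_equal(baseFeForward(rep(0, 384), cfg, p0), matrix(0, 32, 192))

  # constant epoch against a naive O(n*k) convolution loop (identity BN)
  cfg2 <- smallCfg()
  p2 <- initParams(cfg2, seed = 4)
  x <- rep(1.7, cfg2$inputLen)
  xp <- c(rep(0, cfg2$convPad), x, rep(0, cfg2$convPad))
  T <- outputLen(cfg2)
  naive <- matrix(NA_real_, cfg2$nFilters, T)
  for (r in seq_len(cfg2$nFilters)) {
    for (j in seq_len(T)) {
      s <- (j - 1) * cfg2$convStride
      naive[r, j] <- sum(xp[s + seq_len(cfg2$convKernel)] * p2$conv_w[, r]) +
        p2$conv_b[r]
    }
  }
  naive <- naive / sqrt(1 + 1e-5)  # eval-mode batch norm at init stats
  naive <- softThreshold(naive, cfg2$softshrinkLambda)
  expect_equal(baseFeForward(x, cfg2, p2), naive, tolerance = 1e-12)
})

test_that("residual unit reduces to the identity at zero parameters and P = I + O", {
  cfg <- smallCfg()
  I <- matrix(rnorm(cfg$nFilters * outputLen(cfg)), cfg$nFilters)
  out <- rsbuForward(I, cfg, zeroParams(cfg))
  expect_equal(out$U, 0 * I)
  expect_equal(out$O, 0 * I)
  expect_equal(out$P, I)

  for (i in 1:100) {
    p <- initParams(cfg, seed = 100 + i)
    out <- rsbuForward(I, cfg, p)
    expect_equal(out$P - I, out$O, tolerance = 1e-12)
    # shrinkage sparsifies and never increases magnitude
    expect_gte(mean(out$O == 0), mean(out$U == 0))
    expect_true(all(abs(out$O) <= abs(out$U) + 1e-12))
    expect_true(all(out$tau >= 0 & out$tau <= rowMeans(abs(out$U)) + 1e-12))
  }
  expect_error(rsbuForward(I[1:3, ], cfg, initParams(cfg, 1)), "channels")
})

test_that("full forward pass: shapes, softmax normalization, head-logit oracle", {
  cfg <- modelConfig()
  p <- initParams(cfg, seed = 6)
  tr <- modelForward(rnorm(384), cfg, p)
  expect_equal(dim(tr$I), c(32L, 192L))
  expect_equal(dim(tr$P), c(32L, 192L))
  expect_length(tr$gap, 32)
  expect_length(tr$logits, 2)
  expect_length(tr$probs, 2)

  # probabilities sum to 1 over 1000 random inputs (batched)
  X <- matrix(rnorm(1000 * 384), 1000)
  fw <- drowsEEG:::cppForward(X, p, cfg, FALSE, FALSE)
  expect_true(all(abs(rowSums(fw$probs) - 1) < 1e-9))

  # independent dot-product loop recomputes the logits
  for (i in 1:50) {
    tr <- modelForward(X[i, ], cfg, p)
    expect_equal(tr$gap, rowMeans(tr$P), tolerance = 1e-9)
    for (c0 in 1:2) {
      m <- 0
      for (k in 1:32) m <- m + p$head_w[k, c0] * tr$gap[k]
      expect_equal(tr$logits[c0], m + p$head_b[c0], tolerance = 1e-6)
    }
  }
})

test_that("evaluation-mode forward passes are bit-identical", {
  cfg <- smallCfg()
  p <- initParams(cfg, seed = 8)
  x <- rnorm(cfg$inputLen)
  expect_identical(modelForward(x, cfg, p), modelForward(x, cfg, p))
})

test_that("temporal axis is halved by the extractor and preserved by the residual unit", {
  for (seed in 1:3) {
    cfg <- modelConfig()
    p <- initParams(cfg, seed = seed)
    tr <- modelForward(rnorm(384), cfg, p)
    expect_equal(ncol(tr$I), 192L)
    expect_equal(dim(tr$U), dim(tr$I))
    expect_equal(dim(tr$P), dim(tr$I))
  }
})

test_that("compiled engine agrees with the plain-R reference implementation", {
  cfg <- modelConfig()
  p <- initParams(cfg, seed = 11)
  X <- matrix(rnorm(8 * 384), 8)
  fR <- drowsEEG:::forwardBatch(X, p, cfg, training = FALSE)
  fC <- drowsEEG:::cppForward(X, p, cfg, FALSE, TRUE)
  expect_equal(fR$probs, fC$probs, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(fR$se$tau, fC$tau, tolerance = 1e-12, ignore_attr = TRUE)
  # layouts differ (sample-fastest vs time-fastest); compare one sample
  n <- nrow(X); T <- 192
  expect_equal(fR$P[seq(1, by = n, length.out = T), ], fC$P[1:T, ],
               tolerance = 1e-12, ignore_attr = TRUE)

  # gradients: compiled backward vs reference backward (training mode)
  cfg2 <- smallCfg(dropoutP = 0)
  p2 <- initParams(cfg2, seed = 3)
  X2 <- matrix(rnorm(6 * 96), 6)
  y2 <- c(0L, 1L, 0L, 1L, 1L, 0L)
  fw <- drowsEEG:::forwardBatch(X2, p2, cfg2, training = TRUE)
  q <- drowsEEG:::smoothTargets(y2, 0.1, 2)
  gR <- drowsEEG:::backwardBatch(fw, p2, cfg2, (fw$probs - q) / 6)
  gC <- drowsEEG:::cppGrads(X2, y2, p2, cfg2, 0.1, TRUE)
  for (nm in names(gR))
    expect_equal(as.numeric(gR[[nm]]), as.numeric(gC[[nm]]),
                 tolerance = 1e-10, label = nm)
})

test_that("parameter accounting matches the layer-by-layer ledger", {
  cfg <- modelConfig()
  n <- countParameters(cfg)
  b <- attr(n, "breakdown")
  expect_equal(b$basefe, 2144L)  # 1*32*64 + 32 conv, 2*32 batch norm
  expect_equal(b$head, 66L)      # 32*2 + 2
  expect_equal(as.integer(n), 5554L)
  # channel-shared variant restores dimensionality to a single threshold
  nCS <- countParameters(modelConfig(thresholdMode = "CS"))
  expect_equal(as.integer(n) - as.integer(nCS),
               attr(n, "breakdown")$se - attr(nCS, "breakdown")$se)
  # count equals the number of trainable scalars actually allocated
  p <- initParams(cfg, seed = 1)
  expect_equal(sum(lengths(p[drowsEEG:::trainableNames(p)])), as.integer(n))
})
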