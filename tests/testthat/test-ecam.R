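# Class activation mapping, z-scoring, duplication upsampling and the
# Welch relative band power.

test_that("class activation map is the weighted channel sum", {
  h <- rbind(c(1, 2, 3), c(4, 5, 6))
  W <- cbind(c(1, -1), c(0.5, 0.5))
  expect_equal(classActivationMap(h, W, 0), c(-3, -3, -3))
  expect_equal(classActivationMap(h, 0 * W, 1), c(0, 0, 0))
  expect_error(classActivationMap(h, W, 2), "out of range")
  # linearity in the head weights
  W2 <- cbind(c(2, 1), c(0, 0))
  expect_equal(classActivationMap(h, W + W2, 0),
               classActivationMap(h, W, 0) + classActivationMap(h, W2, 0))
})

test_that("temporal mean of the raw map plus bias recovers the logit", {
  cfg <- smallCfg()
  p <- initParams(cfg, seed = 13)
  X <- matrix(rnorm(1000 * cfg$inputLen), 1000)
  fw <- drowsEEG:::cppForward(X, p, cfg, FALSE, TRUE)
  T <- fw$T
  for (c0 in 0:1) {
    v <- fw$P %*% p$head_w[, c0 + 1]
    mapMeans <- colMeans(matrix(v, T, 1000))
    expect_equal(mapMeans + p$head_b[c0 + 1], fw$logits[, c0 + 1],
                 tolerance = 1e-6)
  }
})

test_that("z-score uses the population standard deviation with a constant guard", {
  expect_equal(zscoreVec(c(1, 2, 3)), c(-1, 0, 1) * sqrt(1.5))
  expect_equal(round(zscoreVec(c(1, 2, 3)), 4), c(-1.2247, 0, 1.2247))
  expect_equal(zscoreVec(rep(2.5, 10)), rep(0, 10))
  v <- zscoreVec(rnorm(500))
  expect_equal(mean(v), 0, tolerance = 1e-12)
  expect_equal(mean(v^2), 1, tolerance = 1e-12)
  expect_error(zscoreVec(1), "length")
})

test_that("duplication upsampling repeats elements in order", {
  expect_equal(upsampleDuplicate(c(1, 2, 3), 2), c(1, 1, 2, 2, 3, 3))
  v <- rnorm(10)
  expect_identical(upsampleDuplicate(v, 1), v)
  up <- upsampleDuplicate(rnorm(192), 2)
  expect_length(up, 384)
  # multiset preserved with multiplicity = factor
  v <- c(1, 1, 2, 7)
  expect_equal(as.vector(table(upsampleDuplicate(v, 3))),
               3 * as.vector(table(v)))
  expect_error(upsampleDuplicate(v, 1.5), "positive integer")
})

test_that("heatmaps are input-length, deterministic and class-resolved", {
  net <- synthNet()
  x <- epochSignals(heldOutSet())[1, ]
  hm <- ecam(net, x, class = 1)
  expect_length(hm$upsampled, 384)
  expect_length(hm$rawMap, 192)
  expect_equal(hm$upsampled, upsampleDuplicate(hm$zscored, 2))
  expect_identical(hm, ecam(net, x, class = 1))
  pred <- ecam(net, x, class = "predicted")
  expect_equal(pred$class, which.max(hm$trace$probs) - 1L)
  expect_error(ecam(new("DrowsyNet", config = modelConfig(),
                        params = initParams(modelConfig(), 1),
                        freezeMask = matrix(0, 0, 0), history = numeric(0),
                        trained = FALSE), x), "trained")
})

test_that("relative band power concentrates on a pure tone and partitions to one", {
  t <- (0:383) / 128
  bp <- relativeBandPower(sin(2 * pi * 10 * t))
  expect_gt(bp[["alpha"]], 0.9)
  for (i in 1:20) {
    bp <- relativeBandPower(rnorm(384))
    expect_equal(sum(bp), 1, tolerance = 1e-9)
  }
  expect_error(relativeBandPower(rnorm(50)), "segment")
})

test_that("white-noise band fractions are proportional to bandwidth", {
  set.seed(0)
  acc <- c(delta = 0, theta = 0, alpha = 0, beta = 0)
  n <- 10000L
  for (i in seq_len(n)) acc <- acc + relativeBandPower(rnorm(384))
  frac <- acc / n
  widths <- c(delta = 3, theta = 4, alpha = 4, beta = 18) / 29
  expect_true(all(abs(frac - widths) / widths < 0.10))
})
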