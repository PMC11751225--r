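# Training: freeze mask, label-smoothed loss, optimization contracts,
# evaluation metrics and the leave-one-subject-out protocol.

test_that("freeze mask: boundary thresholds and the binomial frozen fraction", {
  expect_true(all(makeFreezeMask(c(32, 2), t = 0, seed = 1)$mask == 1))
  expect_true(all(makeFreezeMask(c(32, 2), t = 1, seed = 1)$mask == 0))
  expect_error(makeFreezeMask(c(32, 2), t = 1.2), "\\[0, 1\\]")

  set.seed(42)
  frozen <- vapply(1:10000, function(i)
    mean(makeFreezeMask(c(32, 2), t = 0.2)$mask == 0), 0)
  se <- sqrt(0.2 * 0.8 / (64 * 10000))
  expect_lt(abs(mean(frozen) - 0.2), 3 * se)
})

test_that("label-smoothed loss: uniform floor, hand-worked case, alpha = 0 limit", {
  for (y in 0:1) for (a in c(0, 0.1, 0.3))
    expect_equal(labelSmoothedLoss(c(0.5, 0.5), y, a), log(2))
  hand <- -(0.95 * log(0.9) + 0.05 * log(0.1))
  expect_equal(labelSmoothedLoss(c(0.9, 0.1), 0, alpha = 0.1), hand)
  expect_equal(round(hand, 4), 0.2152)
  p <- c(0.73, 0.27)
  expect_equal(labelSmoothedLoss(p, 1, alpha = 0), -log(p[2]))
  expect_error(labelSmoothedLoss(p, 2, 0.1), "invalid class index")
})

test_that("training is reproducible from the seed and requires both classes", {
  es <- tinySeparableSet()
  tc <- trainConfig(nEpochs = 2L, batchSize = 20L, seed = 5L)
  n1 <- trainModel(es, modelConfig(), tc)
  n2 <- trainModel(es, modelConfig(), tc)
  expect_identical(n1@params, n2@params)
  tc$seed <- 6L
  n3 <- trainModel(es, modelConfig(), tc)
  expect_false(identical(n1@params, n3@params))
  onlyDrowsy <- subsetEpochs(es, epochLabels(es) == 1L)
  expect_error(trainModel(onlyDrowsy, modelConfig(), tc), "degenerate")
})

test_that("frozen head weights are bit-identical before and after training", {
  es <- tinySeparableSet(n = 60L)
  cfg <- modelConfig()
  # full freeze: the head never moves
  tc <- trainConfig(nEpochs = 3L, batchSize = 20L, freezeThreshold = 1,
                    seed = 2L)
  init <- drowsEEG:::withSeed(tc$seed, initParams(cfg))
  net <- trainModel(es, cfg, tc)
  expect_identical(net@params$head_w, init$head_w)
  # partial freeze: zero drift exactly on the masked entries
  tc$freezeThreshold <- 0.2
  net <- trainModel(es, cfg, tc)
  frozen <- net@freezeMask == 0
  expect_true(any(frozen))
  expect_identical(net@params$head_w[frozen], init$head_w[frozen])
  expect_false(any(net@params$head_w[!frozen] == init$head_w[!frozen]))
})

test_that("training loss decreases on a linearly separable set", {
  es <- tinySeparableSet(n = 120L, seed = 0L)
  net <- trainModel(es, modelConfig(),
                    trainConfig(nEpochs = 8L, batchSize = 30L, seed = 0L))
  h <- net@history
  steps <- diff(h)
  expect_gte(mean(steps <= 0), 0.8)
  expect_lt(h[length(h)], h[1])
})

test_that("evaluation metrics match a hand confusion matrix", {
  sc <- drowsEEG:::scorePredictions
  m <- sc(c(1, 1, 0, 0), c(1, 0, 0, 0))  # TP=1 FP=0 FN=1
  expect_equal(m$accuracy, 75.0)
  expect_equal(m$f1, 100 * 2 / 3, tolerance = 1e-9)
  expect_equal(sum(m$confusion), 4L)
  perfect <- sc(c(0, 1, 0, 1), c(0, 1, 0, 1))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$f1, 100)
  # all-alert predictions: zero recall handled without exceptions
  allAlert <- sc(c(0, 1, 1, 0), c(0, 0, 0, 0))
  expect_equal(allAlert$f1, 0)
})

test_that("LOSO folds partition subjects correctly", {
  spec <- syntheticSpec(nSubjects = 3L, epochsPerClass = 12L, seed = 5L)
  es <- simulateEpochSet(spec)
  cfg <- modelConfig(nFilters = 8L)
  res <- losoCV(es, model = cfg,
                train = trainConfig(nEpochs = 1L, batchSize = 24L, seed = 1L))
  expect_equal(nrow(res$folds), 3L)
  expect_setequal(res$folds$subject, 1:3)
  expect_equal(sum(res$folds$n), ncol(es))

  res2 <- losoCV(es, model = cfg,
                 train = trainConfig(nEpochs = 1L, batchSize = 24L, seed = 1L),
                 nRepeats = 2L)
  expect_equal(nrow(res2$folds), 6L)
  expect_equal(as.vector(table(res2$folds$subject)), c(2L, 2L, 2L))

  other <- simulateEpochSet(syntheticSpec(nSubjects = 4L, epochsPerClass = 6L,
                                          seed = 6L))
  expect_error(losoCV(es, other), "protocol error")
})

test_that("dual-pool LOSO trains on one pool and tests on the other", {
  tr <- simulateEpochSet(syntheticSpec(nSubjects = 2L, epochsPerClass = 15L,
                                       seed = 8L))
  te <- simulateEpochSet(syntheticSpec(nSubjects = 2L, epochsPerClass = 10L,
                                       unbalanced = TRUE, seed = 9L))
  res <- losoCV(tr, te, model = modelConfig(),
                train = trainConfig(nEpochs = 1L, batchSize = 15L, seed = 1L))
  expect_equal(sum(res$folds$n), ncol(te))  # test counts come from testPool
})
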