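# Synthetic EEG generator: background spectrum, event injection,
# dataset structure and class separability.

test_that("pink noise is seeded, unit-RMS and has a 1/f spectrum", {
  expect_identical(pinkNoise(384, seed = 4), pinkNoise(384, seed = 4))
  expect_false(identical(pinkNoise(384, seed = 4), pinkNoise(384, seed = 5)))
  expect_equal(sqrt(mean(pinkNoise(384, seed = 1)^2)), 1, tolerance = 1e-6)
  expect_equal(mean(pinkNoise(384, seed = 1)), 0, tolerance = 1e-9)
  expect_error(pinkNoise(1), "n >= 2")

  # average Welch spectrum over 500 draws; log-log slope should be about -1
  set.seed(10)
  acc <- NULL
  for (i in 1:500) {
    ps <- welchPSD(pinkNoise(384), fs = 128)
    acc <- if (is.null(acc)) ps$psd else acc + ps$psd
  }
  keep <- ps$freq >= 2 & ps$freq <= 40
  fit <- stats::lm(log(acc[keep]) ~ log(ps$freq[keep]))
  expect_lt(abs(unname(coef(fit)[2]) + 1), 0.15)
})

test_that("event injection is local and amplitude-faithful", {
  x <- pinkNoise(384, seed = 2)
  out <- injectBurst(x, "alpha_spindle", c(100, 250), freq = 10,
                     amplitude = 0, seed = 1)
  expect_identical(out$signal, x)
  out <- injectBurst(x, "theta_delta", c(100, 250), freq = 3, amplitude = 2,
                     seed = 1)
  expect_identical(out$signal[c(1:99, 251:384)], x[c(1:99, 251:384)])
  expect_false(identical(out$signal[100:250], x[100:250]))
  expect_equal(out$event$kind, "theta_delta")
  expect_error(injectBurst(x, "beta", c(380, 500), freq = 20), "out of range")
  expect_error(injectBurst(x, "humming", c(1, 50)), "arg")
})

test_that("an injected alpha spindle raises relative alpha power", {
  gain <- numeric(200)
  for (i in 1:200) {
    x <- pinkNoise(384, seed = 1000 + i)
    before <- relativeBandPower(x)[["alpha"]]
    out <- injectBurst(x, "alpha_spindle", c(129, 256), freq = 10,
                       amplitude = 2, seed = i)
    gain[i] <- relativeBandPower(out$signal)[["alpha"]] - before
  }
  expect_gte(mean(gain), 0.15)
})

test_that("generated datasets match the requested structure and are reproducible", {
  spec <- syntheticSpec(nSubjects = 3L, epochsPerClass = 10L, seed = 21L)
  es <- simulateEpochSet(spec)
  expect_s4_class(es, "EpochSet")
  expect_equal(ncol(es), 60L)
  expect_equal(nrow(es), 384L)
  expect_equal(sort(unique(subjectIds(es))), 1:3)
  expect_equal(as.vector(table(epochLabels(es))), c(30L, 30L))
  expect_identical(epochSignals(simulateEpochSet(spec)), epochSignals(es))
  expect_false(identical(
    epochSignals(simulateEpochSet(syntheticSpec(nSubjects = 3L,
                                                epochsPerClass = 10L,
                                                seed = 22L))),
    epochSignals(es)))

  ev <- epochEvents(es)
  expect_true(all(ev$start >= 1 & ev$end <= 384 & ev$end > ev$start))
  expect_true(all(ev$kind %in% c("theta_delta", "alpha_spindle", "beta",
                                 "blink")))
  # every drowsy epoch is annotated with at least one drowsiness event and
  # alert epochs carry a beta rhythm; no drowsy-kind event in alert epochs
  y <- epochLabels(es)
  drowsyKinds <- c("theta_delta", "alpha_spindle")
  for (i in seq_len(ncol(es))) {
    kinds <- ev$kind[ev$epoch == i]
    if (y[i] == 1L) {
      expect_gte(sum(kinds %in% drowsyKinds), 1)
    } else {
      expect_true("beta" %in% kinds)
      expect_false(any(kinds %in% drowsyKinds))
    }
  }
})

test_that("unbalanced mode draws varied per-subject class ratios", {
  spec <- syntheticSpec(nSubjects = 6L, epochsPerClass = 30L,
                        unbalanced = TRUE, seed = 31L)
  es <- simulateEpochSet(spec)
  tab <- table(subjectIds(es), epochLabels(es))
  expect_true(all(rowSums(tab) == 60L))   # per-subject totals preserved
  expect_true(all(tab >= 10L))            # both classes always present
  ratios <- tab[, 1] / tab[, 2]
  expect_gt(max(ratios) / min(ratios), 1.5)
})

test_that("drowsy epochs carry more theta+alpha power than alert epochs", {
  es <- simulateEpochSet(syntheticSpec(epochsPerClass = 313L, seed = 41L))
  X <- epochSignals(es)
  y <- epochLabels(es)
  ta <- vapply(seq_len(nrow(X)), function(i) {
    bp <- relativeBandPower(X[i, ])
    bp[["theta"]] + bp[["alpha"]]
  }, 0)
  expect_gte(mean(ta[y == 1L]) - mean(ta[y == 0L]), 0.1)
})
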