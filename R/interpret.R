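#' Sine-plus-noise perturbation
#'
#' Adds a seeded nonlinear perturbation whose strength scales with both the
#' scale factor `n` and the epoch's own RMS, so perturbed samples stay close
#' to the original signal distribution:
#' `x'_i = x_i + n * gamma * RMS(x) * (sin(2 pi f i / fs + phi) + xi_i)`
#' with `phi` uniform on `[0, 2 pi)` and `xi` standard normal.
#'
#' @param epoch Numeric signal.
#' @param n Nonnegative perturbation scale; `n = 0` returns `epoch` exactly.
#' @param sineFreq Sine frequency in Hz.
#' @param gamma Base amplitude as a fraction of the epoch RMS.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed (deterministic output for a fixed
#'   `(epoch, n, seed)`).
#' @return Perturbed epoch, same length.
#' @export
perturbEpoch <- function(epoch, n, sineFreq = 5, gamma = 0.05, fs = 128,
                         seed = NULL) {
  if (n < 0) stopf("perturbation scale n must be >= 0")
  L <- length(epoch)
  withSeed(seed, {
    phi <- runif(1, 0, 2 * pi)
    xi <- rnorm(L)
    epoch + n * gamma * rmsValue(epoch) *
      (sin(2 * pi * sineFreq * (seq_len(L) - 1L) / fs + phi) + xi)
  })
}

#' Pearson correlation with a constant-input guard
#'
#' @param a,b Numeric vectors of equal length >= 2.
#' @return Product-moment correlation in `[-1, 1]`; 0 (with a warning) when
#'   either input is constant.
#' @export
pearsonCorr <- function(a, b) {
  if (length(a) != length(b)) stopf("pearsonCorr: length mismatch")
  if (length(a) < 2) stopf("pearsonCorr needs length >= 2")
  if (sd(a) == 0 || sd(b) == 0) {
    warning("constant input to pearsonCorr; returning 0")
    return(0)
  }
  cor(a, b)
}

#' Perturbation sensitivity test
#'
#' Measures heatmap stability under input perturbations: for each sample and
#' each scale, `copies` perturbed versions are generated, their z-scored
#' class activation maps computed, and the Pearson correlation with the
#' unperturbed map recorded. Both the mean and the best (maximum) correlation
#' per scale are reported, averaged over samples. Maps use each sample's
#' labeled class.
#'
#' @param net A trained [DrowsyNet-class].
#' @param samples An [EpochSet-class] of labeled samples.
#' @param scales Integer perturbation scales (default 1 to 5).
#' @param copies Perturbed copies per sample and scale.
#' @param sineFreq,gamma Perturbation parameters (see [perturbEpoch()]).
#' @param seed Integer seed; every sample reuses the same perturbation draws,
#'   so identical samples give identical correlation vectors.
#' @return data.frame with columns `scale`, `meanPCC`, `maxPCC`; per-sample
#'   mean correlations are attached as attribute `"perSample"` (samples x
#'   scales).
#' @export
sensitivityTest <- function(net, samples, scales = 1:5, copies = 20L,
                            sineFreq = 5, gamma = 0.05, seed = 1L) {
  if (!net@trained) stopf("sensitivity test needs a trained model")
  X <- epochSignals(samples)
  y <- epochLabels(samples)
  fs <- samplingRate(samples)
  nS <- nrow(X)
  meanM <- matrix(NA_real_, nS, length(scales))
  maxM <- matrix(NA_real_, nS, length(scales))
  for (i in seq_len(nS)) {
    x0 <- X[i, ]
    base <- ecamBatch(net, matrix(x0, 1), y[i])$maps[1, ]
    for (j in seq_along(scales)) {
      P <- withSeed(seed + scales[j], {
        t(vapply(seq_len(copies), function(b)
          perturbEpoch(x0, scales[j], sineFreq, gamma, fs), numeric(length(x0))))
      })
      maps <- ecamBatch(net, P, rep(y[i], copies))$maps
      pcc <- apply(maps, 1, function(m)
        suppressWarnings(pearsonCorr(base, m)))
      meanM[i, j] <- mean(pcc)
      maxM[i, j] <- max(pcc)
    }
  }
  out <- data.frame(scale = scales, meanPCC = colMeans(meanM),
                    maxPCC = colMeans(maxM))
  attr(out, "perSample") <- meanM
  out
}

#' Deletion test
#'
#' Saliency-quality check: timepoints are ranked by their heatmap value in
#' descending order (ties broken by time index, so the deletion sets are
#' nested across fractions); for each deletion fraction the top-ranked
#' timepoints are set to zero and the model's probability for the sample's
#' labeled class is recorded. A sharp probability drop indicates that the
#' heatmap identified genuinely decision-relevant samples. Ranking operates
#' on the upsampled input-resolution heatmap so ranks align one-to-one with
#' timepoints.
#'
#' @param net A trained [DrowsyNet-class].
#' @param samples An [EpochSet-class].
#' @param fractions Strictly increasing deletion fractions in `[0, 1]`; the
#'   baseline fraction 0 is always prepended.
#' @return data.frame with columns `fraction` and `meanProb` (mean predicted
#'   probability of the labeled class); per-sample probabilities attached as
#'   attribute `"perSample"`.
#' @export
deletionTest <- function(net, samples, fractions = seq(0.05, 0.5, by = 0.05)) {
  if (!net@trained) stopf("deletion test needs a trained model")
  if (any(fractions < 0 | fractions > 1) || is.unsorted(fractions, strictly = TRUE))
    stopf("deletion fractions must be strictly increasing within [0, 1]")
  fractions <- c(0, fractions)
  X <- epochSignals(samples)
  y <- epochLabels(samples)
  L <- ncol(X)
  probs <- matrix(NA_real_, nrow(X), length(fractions))
  for (i in seq_len(nrow(X))) {
    heat <- ecam(net, X[i, ], class = y[i])$upsampled
    ord <- order(-heat, seq_len(L))  # stable: ties keep time order
    V <- matrix(X[i, ], length(fractions), L, byrow = TRUE)
    for (j in seq_along(fractions)) {
      k <- round(fractions[j] * L)
      if (k > 0) V[j, ord[seq_len(k)]] <- 0
    }
    probs[i, ] <- predictProbs(net, V)[, y[i] + 1L]
  }
  out <- data.frame(fraction = fractions, meanProb = colMeans(probs))
  attr(out, "perSample") <- probs
  out
}
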