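#' Class activation map over the feature axis
#'
#' The per-timepoint contribution of the residual feature map to a class
#' logit: `M_c(j) = sum_k w[k, c] * h[k, j]`, where `h` is the residual
#' unit's output and `w` the classification-head weights. The head bias and
#' the pooling factor are omitted, so the temporal mean of the map equals the
#' class logit minus the bias — an identity used as an internal consistency
#' check.
#'
#' @param trace A `forwardTrace` from [modelForward()], or a channels-by-time
#'   feature map `h` directly.
#' @param headW Head weight matrix, `nFilters x nClasses`.
#' @param classIndex 0-based class index (0 alert, 1 drowsy).
#' @return Numeric vector of length `T` (the raw activation map).
#' @examples
#' h <- rbind(c(1, 2, 3), c(4, 5, 6))
#' classActivationMap(h, cbind(c(1, -1)), 0)  # -3 -3 -3
#' @export
classActivationMap <- function(trace, headW, classIndex) {
  h <- if (is.list(trace)) trace$P else trace
  if (classIndex < 0 || classIndex >= ncol(headW))
    stopf("class index %d out of range", classIndex)
  as.vector(crossprod(h, headW[, classIndex + 1L]))
}

#' Z-score normalization
#'
#' Centers and scales by the population standard deviation; a constant input
#' maps to all zeros rather than dividing by zero.
#'
#' @param v Numeric vector of length >= 2.
#' @return Normalized vector (mean 0, unit population variance).
#' @export
zscoreVec <- function(v) {
  if (length(v) < 2) stopf("zscoreVec needs length >= 2")
  s <- sqrt(mean((v - mean(v))^2))
  if (s == 0) return(rep(0, length(v)))
  (v - mean(v)) / s
}

#' Duplication upsampling
#'
#' Restores a feature-resolution map to input resolution by repeating each
#' element `factor` consecutive times (order preserved), e.g. a length-192
#' map becomes length 384 at factor 2.
#'
#' @param v Numeric vector.
#' @param factor Positive integer repetition factor.
#' @return Vector of length `length(v) * factor`.
#' @examples
#' upsampleDuplicate(c(1, 2, 3), 2)  # 1 1 2 2 3 3
#' @export
upsampleDuplicate <- function(v, factor = 2L) {
  if (length(factor) != 1 || factor < 1 || factor != round(factor))
    stopf("upsampling factor must be a positive integer")
  rep(v, each = as.integer(factor))
}

#' EEG class activation heatmap
#'
#' Runs an evaluation-mode forward pass, forms the class activation map over
#' the residual feature map, z-scores it at feature resolution (length 192),
#' and duplicates each element back to input resolution (length 384). The
#' result localizes the waveform stretches that drive the class logit.
#'
#' @param net A trained [DrowsyNet-class].
#' @param epoch Numeric vector of length `inputLen`.
#' @param class 0, 1, or `"predicted"` (argmax class).
#' @return List of class `"ecamHeatmap"`: `class`, `rawMap` (length `T`),
#'   `zscored` (length `T`), `upsampled` (input length), `logit`, `prob`,
#'   `weights`, `bias`, `trace`.
#' @export
ecam <- function(net, epoch, class = "predicted") {
  if (!net@trained) stopf("ecam needs a trained model")
  trace <- modelForward(epoch, net@config, net@params, training = FALSE)
  c0 <- if (identical(class, "predicted")) which.max(trace$probs) - 1L
        else as.integer(class)
  raw <- classActivationMap(trace, net@params$head_w, c0)
  z <- zscoreVec(raw)
  fac <- net@config$inputLen %/% length(raw)
  structure(list(class = c0, rawMap = raw, zscored = z,
                 upsampled = upsampleDuplicate(z, fac),
                 logit = trace$logits[c0 + 1L], prob = trace$probs[c0 + 1L],
                 weights = net@params$head_w[, c0 + 1L],
                 bias = net@params$head_b[c0 + 1L], trace = trace),
            class = "ecamHeatmap")
}

# batched raw CAMs, one class per sample: returns n x T matrix (zscored rows)
ecamBatch <- function(net, X, classes) {
  fw <- cppForward(X, net@params, net@config, training = FALSE, trace = TRUE)
  n <- nrow(X)
  W <- net@params$head_w
  maps <- matrix(NA_real_, n, fw$T)
  for (c0 in unique(classes)) {
    v <- fw$P %*% W[, c0 + 1L]
    m <- t(matrix(v, fw$T, n))  # engine rows are time-fastest within sample
    rows <- which(classes == c0)
    maps[rows, ] <- m[rows, , drop = FALSE]
  }
  list(maps = t(apply(maps, 1, zscoreVec)), probs = fw$probs)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: the signal is split into overlapping
#' segments, each demeaned, Hann-windowed and Fourier transformed; the
#' one-sided periodograms are averaged.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param segment Segment length in samples (default one second).
#' @param overlap Fractional overlap between segments.
#' @return List with `freq` (Hz) and `psd` (power per Hz).
#' @export
welchPSD <- function(x, fs = 128, segment = fs, overlap = 0.5) {
  n <- length(x)
  segment <- as.integer(segment)
  if (n < segment) stopf("signal shorter than one Welch segment (%d)", segment)
  step <- max(1L, as.integer(segment * (1 - overlap)))
  starts <- seq(1L, n - segment + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(segment - 1)) / segment)
  scale <- 1 / (fs * sum(w^2))
  nf <- segment %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + segment - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- abs(fft(seg))^2 * scale
    p <- p[seq_len(nf)]
    p[2:(nf - 1L)] <- 2 * p[2:(nf - 1L)]
    acc <- acc + p
  }
  list(freq = (seq_len(nf) - 1L) * fs / segment, psd = acc / length(starts))
}

trapz <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)]) / 2)

#' Relative band power
#'
#' Welch spectral estimate integrated (trapezoid rule) over the canonical
#' bands delta 1-4, theta 4-8, alpha 8-12 and beta 12-30 Hz, each normalized
#' by the total 1-30 Hz power, so the four fractions sum to one.
#'
#' @param epoch Numeric signal (>= one Welch segment).
#' @param fs Sampling rate in Hz.
#' @param bands Named list of `c(lo, hi)` band edges in Hz.
#' @param segment,overlap Welch parameters (see [welchPSD()]).
#' @return Named numeric vector of band fractions in `[0, 1]`, with the PSD
#'   attached as attribute `"psd"`.
#' @examples
#' x <- sin(2 * pi * 10 * (0:383) / 128)
#' relativeBandPower(x)["alpha"]  # > 0.9
#' @export
relativeBandPower <- function(epoch, fs = 128,
                              bands = list(delta = c(1, 4), theta = c(4, 8),
                                           alpha = c(8, 12), beta = c(12, 30)),
                              segment = fs, overlap = 0.5) {
  ps <- welchPSD(epoch, fs, segment, overlap)
  bandPower <- function(b) {
    keep <- ps$freq >= b[1] & ps$freq <= b[2]
    if (sum(keep) < 2) return(0)
    trapz(ps$freq[keep], ps$psd[keep])
  }
  lo <- min(vapply(bands, `[`, 0, 1))
  hi <- max(vapply(bands, `[`, 0, 2))
  total <- bandPower(c(lo, hi))
  frac <- vapply(bands, bandPower, 0) / max(total, .Machine$double.xmin)
  attr(frac, "psd") <- ps
  frac
}
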