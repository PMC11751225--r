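#' Pink (1/f) background noise
#'
#' Spectrally shaped Gaussian noise emulating the broadband 1/f background of
#' resting EEG: a white-noise spectrum is scaled by `1/sqrt(f)` (so the power
#' spectrum falls as `1/f`), inverse transformed, demeaned and normalized to
#' unit RMS.
#'
#' @param n Number of samples (>= 2).
#' @param seed Optional integer seed.
#' @return Zero-mean numeric vector with RMS 1.
#' @export
pinkNoise <- function(n, seed = NULL) {
  if (n < 2) stopf("pinkNoise needs n >= 2")
  withSeed(seed, {
    w <- rnorm(n)
    f <- fft(w)
    k <- 0:(n - 1)
    fbin <- pmin(k, n - k)  # symmetric frequency magnitude per bin
    sc <- ifelse(fbin > 0, 1 / sqrt(fbin), 0)
    x <- Re(fft(f * sc, inverse = TRUE)) / n
    x <- x - mean(x)
    x / rmsValue(x)
  })
}

hannWindow <- function(n) {
  if (n == 1) return(1)
  0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Inject an oscillatory event into a signal
#'
#' Adds a class-discriminative event on a sample interval, leaving the signal
#' outside the interval untouched:
#' * `"alpha_spindle"` / `"beta"`: Hann-windowed sinusoid at `freq` with a
#'   random phase,
#' * `"theta_delta"`: Hann-windowed slow oscillation whose frequency is
#'   re-jittered every half cycle (+/- 20%), giving an irregular rhythmic
#'   burst,
#' * `"blink"`: a monophasic Gaussian peak (width 0.05 s SD) centred on the
#'   interval, mimicking an ocular artifact.
#'
#' @param signal Numeric vector.
#' @param kind One of `"alpha_spindle"`, `"theta_delta"`, `"beta"`, `"blink"`.
#' @param interval `c(start, end)`, 1-based inclusive sample indices.
#' @param freq Oscillation frequency in Hz (ignored for `"blink"`).
#' @param amplitude Peak amplitude of the event envelope.
#' @param fs Sampling rate in Hz.
#' @param seed Optional integer seed.
#' @return List with `signal` (modified vector) and `event` (one-row
#'   data.frame: `start`, `end`, `kind`).
#' @export
injectBurst <- function(signal, kind, interval, freq = NULL, amplitude = 1,
                        fs = 128, seed = NULL) {
  kind <- match.arg(kind, c("alpha_spindle", "theta_delta", "beta", "blink"))
  s <- as.integer(interval[1]); e <- as.integer(interval[2])
  if (s < 1 || e > length(signal) || e <= s)
    stopf("event interval [%d, %d] out of range for a length-%d signal",
          s, e, length(signal))
  len <- e - s + 1L
  burst <- withSeed(seed, {
    if (kind == "blink") {
      t <- seq_len(len) - (len + 1) / 2
      exp(-t^2 / (2 * (0.05 * fs)^2))
    } else if (kind == "theta_delta") {
      phi <- runif(1, 0, 2 * pi)
      finst <- numeric(len)
      i <- 1L
      while (i <= len) {
        fHalf <- freq * runif(1, 0.8, 1.2)
        half <- max(1L, round(fs / (2 * fHalf)))
        finst[i:min(len, i + half - 1L)] <- fHalf
        i <- i + half
      }
      hannWindow(len) * sin(phi + cumsum(2 * pi * finst / fs))
    } else {
      phi <- runif(1, 0, 2 * pi)
      hannWindow(len) * sin(2 * pi * freq * (seq_len(len) - 1L) / fs + phi)
    }
  })
  signal[s:e] <- signal[s:e] + amplitude * burst
  list(signal = signal,
       event = data.frame(start = s, end = e, kind = kind))
}

#' Generate a labeled multi-subject synthetic EEG dataset
#'
#' Emulates the structure of preprocessed sustained-attention driving
#' recordings at desk scale: each subject contributes 3-s single-channel
#' epochs over a pink-noise background with subject-specific gain, peak alpha
#' frequency and background level. Drowsy epochs carry one or two drowsiness
#' events (theta-delta bursts or alpha spindles at the subject's alpha
#' frequency, amplitude `burstSNR` times the background RMS); alert epochs
#' carry a sustained beta rhythm and, occasionally, a blink-like peak — an
#' artifact a robust classifier should not lean on. Every injected event is
#' recorded in the ground-truth annotation table, enabling localization
#' scoring of the interpretation maps. Balanced mode yields equal class
#' counts per subject; unbalanced mode draws per-subject alert:drowsy ratios
#' log-uniformly from `imbalanceRange`.
#'
#' @param spec A [syntheticSpec()].
#' @return An [EpochSet-class] with provenance `"synthetic"` and an event
#'   annotation table in `metadata(x)$events`; byte-identical for a fixed
#'   `spec$seed`.
#' @export
simulateEpochSet <- function(spec = syntheticSpec()) {
  L <- as.integer(spec$fs * spec$duration)
  withSeed(spec$seed, {
    signals <- list(); labels <- integer(0); subjects <- integer(0)
    events <- list()
    epi <- 0L
    for (sj in seq_len(spec$nSubjects)) {
      gain <- rlnorm(1, 0, spec$subjectGainSD)
      alphaF <- runif(1, spec$alphaFreqRange[1], spec$alphaFreqRange[2])
      bgLevel <- rlnorm(1, 0, spec$bgJitterSD)
      total <- 2L * spec$epochsPerClass
      if (spec$unbalanced) {
        r <- exp(runif(1, log(spec$imbalanceRange[1]),
                       log(spec$imbalanceRange[2])))
        nAlert <- min(max(round(total * r / (1 + r)), 10L), total - 10L)
      } else nAlert <- spec$epochsPerClass
      nDrowsy <- total - nAlert
      for (cls in c(rep(0L, nAlert), rep(1L, nDrowsy))) {
        epi <- epi + 1L
        x <- bgLevel * pinkNoise(L)
        amp <- spec$burstSNR * bgLevel
        if (cls == 1L) {
          nEv <- 1L + rbinom(1, 1, 0.3)
          for (k in seq_len(nEv)) {
            dur <- round(runif(1, spec$burstDuration[1],
                               spec$burstDuration[2]) * spec$fs)
            dur <- min(dur, L - 2L)
            st <- sample.int(L - dur, 1)
            if (runif(1) < spec$drowsyMix) {
              ib <- injectBurst(x, "theta_delta", c(st, st + dur),
                                freq = runif(1, 1.5, 6), amplitude = amp,
                                fs = spec$fs)
            } else {
              ib <- injectBurst(x, "alpha_spindle", c(st, st + dur),
                                freq = alphaF, amplitude = amp, fs = spec$fs)
            }
            x <- ib$signal
            events[[length(events) + 1L]] <- cbind(epoch = epi, ib$event)
          }
        } else {
          ib <- injectBurst(x, "beta", c(1L, L), freq = runif(1, 15, 25),
                            amplitude = spec$betaAmp * bgLevel, fs = spec$fs)
          x <- ib$signal
          events[[length(events) + 1L]] <- cbind(epoch = epi, ib$event)
          if (runif(1) < spec$blinkProb) {
            w <- round(0.3 * spec$fs)
            st <- sample.int(L - w, 1)
            ib <- injectBurst(x, "blink", c(st, st + w),
                              amplitude = 4 * bgLevel, fs = spec$fs)
            x <- ib$signal
            events[[length(events) + 1L]] <- cbind(epoch = epi, ib$event)
          }
        }
        signals[[epi]] <- gain * x
        labels[epi] <- cls
        subjects[epi] <- sj
      }
    }
    EpochSet(do.call(rbind, signals), labels, subjects,
             events = do.call(rbind, events), provenance = "synthetic",
             samplingRate = spec$fs)
  })
}
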