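#' Architectural configuration
#'
#' Collects every architectural hyperparameter of the network: a shallow
#' convolutional feature extractor (stride-2 conv, batch norm, soft-shrink
#' activation, dropout) followed by a residual shrinkage unit whose soft
#' thresholds are learned per channel (`"CW"`) or shared across channels
#' (`"CS"`) by a squeeze-and-excitation branch, global average pooling and an
#' affine classification head.
#'
#' @param inputLen Epoch length in samples (default 384 = 3 s at 128 Hz).
#' @param samplingRate Sampling rate in Hz.
#' @param nFilters Number of convolution filters / feature channels.
#' @param convKernel Kernel length in samples (default 64, half the sampling
#'   rate, so the filter bank resolves rhythms above 2 Hz).
#' @param convStride Convolution stride (default 2, halving the temporal axis).
#' @param convPad Symmetric zero padding per side (default 31 so that
#'   384 maps to exactly 192 output positions).
#' @param softshrinkLambda Soft-shrink activation threshold (>= 0).
#' @param dropoutP Dropout probability in `[0, 1)`.
#' @param seReduction Reduction ratio of the squeeze-and-excitation branch;
#'   must divide `nFilters`.
#' @param thresholdMode `"CW"` (one learned threshold per channel) or
#'   `"CS"` (a single shared threshold).
#' @param nClasses Number of output classes (2: alert / drowsy).
#' @return A validated list of class `"modelConfig"`.
#' @examples
#' cfg <- modelConfig()
#' outputLen(cfg)      # 192
#' countParameters(cfg) # 5554
#' @export
modelConfig <- function(inputLen = 384L, samplingRate = 128, nFilters = 32L,
                        convKernel = 64L, convStride = 2L, convPad = 31L,
                        softshrinkLambda = 0.5, dropoutP = 0.5,
                        seReduction = 2L, thresholdMode = c("CW", "CS"),
                        nClasses = 2L) {
  thresholdMode <- match.arg(thresholdMode)
  cfg <- list(
    inputLen = as.integer(inputLen), samplingRate = samplingRate,
    nFilters = as.integer(nFilters), convKernel = as.integer(convKernel),
    convStride = as.integer(convStride), convPad = as.integer(convPad),
    softshrinkLambda = softshrinkLambda, dropoutP = dropoutP,
    seReduction = as.integer(seReduction), thresholdMode = thresholdMode,
    nClasses = as.integer(nClasses)
  )
  if (cfg$softshrinkLambda < 0) stopf("softshrinkLambda must be >= 0")
  if (cfg$dropoutP < 0 || cfg$dropoutP >= 1) stopf("dropoutP must lie in [0, 1)")
  if (cfg$seReduction < 1 || cfg$nFilters %% cfg$seReduction != 0)
    stopf("seReduction must be a positive divisor of nFilters")
  if (outputLen(cfg) < 1) stopf("configuration yields an empty feature map")
  class(cfg) <- c("modelConfig", "list")
  cfg
}

#' Temporal length of the feature map
#'
#' Output length of the stride-`s` convolution:
#' `T = floor((inputLen + 2 * convPad - convKernel) / convStride) + 1`.
#' With defaults, 384 samples map to T = 192.
#' @param config A [modelConfig()].
#' @return Integer feature-map length.
#' @export
outputLen <- function(config) {
  with(config, (inputLen + 2L * convPad - convKernel) %/% convStride + 1L)
}

#' Training configuration
#'
#' @param learningRate Adam learning rate (default 0.001).
#' @param batchSize Mini-batch size (default 50).
#' @param nEpochs Number of training epochs (default 10).
#' @param freezeThreshold Fraction `t` in `[0, 1]` of head weights frozen by
#'   the random weight-freezing mask (default 0.2).
#' @param labelSmoothing Label-smoothing parameter alpha in `[0, 1)`
#'   (default 0.1).
#' @param seed Integer seed driving initialization, the freeze mask, batch
#'   shuffling and dropout.
#' @return A validated list of class `"trainConfig"`.
#' @export
trainConfig <- function(learningRate = 0.001, batchSize = 50L, nEpochs = 10L,
                        freezeThreshold = 0.2, labelSmoothing = 0.1,
                        seed = 1L) {
  cfg <- list(learningRate = learningRate, batchSize = as.integer(batchSize),
              nEpochs = as.integer(nEpochs), freezeThreshold = freezeThreshold,
              labelSmoothing = labelSmoothing, seed = as.integer(seed))
  if (cfg$learningRate <= 0) stopf("learningRate must be > 0")
  if (cfg$batchSize < 1) stopf("batchSize must be >= 1")
  if (cfg$freezeThreshold < 0 || cfg$freezeThreshold > 1)
    stopf("freezeThreshold must lie in [0, 1]")
  if (cfg$labelSmoothing < 0 || cfg$labelSmoothing >= 1)
    stopf("labelSmoothing must lie in [0, 1)")
  class(cfg) <- c("trainConfig", "list")
  cfg
}

#' Synthetic EEG generator specification
#'
#' Defines the study conditions the generator emulates: multi-subject sets of
#' 3-s single-channel epochs over a pink-noise background, where drowsy
#' epochs carry theta-delta bursts and alpha spindles and alert epochs carry
#' a sustained beta rhythm with occasional blink-like peaks.
#'
#' @param nSubjects Number of subjects (default 8).
#' @param epochsPerClass Epochs per class per subject in balanced mode
#'   (default 100; unbalanced mode keeps the per-subject total).
#' @param fs Sampling rate in Hz (fixed design: 128).
#' @param duration Epoch duration in seconds (3 s, so 384 samples).
#' @param drowsyMix Probability that a drowsy event is a theta-delta burst
#'   (vs. an alpha spindle).
#' @param burstDuration Burst duration range in seconds.
#' @param burstSNR Burst amplitude as a multiple of the background RMS.
#' @param betaAmp Alert beta-rhythm amplitude as a multiple of background RMS.
#' @param blinkProb Probability of a blink artifact in an alert epoch.
#' @param subjectGainSD Log-SD of the per-subject lognormal gain.
#' @param alphaFreqRange Per-subject peak alpha frequency range in Hz.
#' @param bgJitterSD Log-SD of the per-subject background level jitter.
#' @param unbalanced If `TRUE`, per-subject class ratios are drawn from
#'   `imbalanceRange` instead of being 1:1.
#' @param imbalanceRange Range of alert:drowsy imbalance factors sampled
#'   log-uniformly in unbalanced mode.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A validated list of class `"syntheticSpec"`.
#' @export
syntheticSpec <- function(nSubjects = 8L, epochsPerClass = 100L, fs = 128,
                          duration = 3, drowsyMix = 0.5,
                          burstDuration = c(0.5, 1.5), burstSNR = 2,
                          betaAmp = 1, blinkProb = 0.1, subjectGainSD = 0.2,
                          alphaFreqRange = c(9, 11), bgJitterSD = 0.1,
                          unbalanced = FALSE, imbalanceRange = c(0.3, 5.5),
                          seed = 1L) {
  spec <- list(nSubjects = as.integer(nSubjects),
               epochsPerClass = as.integer(epochsPerClass), fs = fs,
               duration = duration, drowsyMix = drowsyMix,
               burstDuration = burstDuration, burstSNR = burstSNR,
               betaAmp = betaAmp, blinkProb = blinkProb,
               subjectGainSD = subjectGainSD, alphaFreqRange = alphaFreqRange,
               bgJitterSD = bgJitterSD, unbalanced = isTRUE(unbalanced),
               imbalanceRange = imbalanceRange, seed = as.integer(seed))
  for (p in c("drowsyMix", "blinkProb"))
    if (spec[[p]] < 0 || spec[[p]] > 1) stopf("%s must lie in [0, 1]", p)
  if (round(spec$fs * spec$duration) != spec$fs * spec$duration)
    stopf("fs * duration must be an integer number of samples")
  class(spec) <- c("syntheticSpec", "list")
  spec
}

# Allowed keys of a run-configuration file, per section.
.runConfigSchema <- list(
  model = names(formals(modelConfig)),
  train = names(formals(trainConfig)),
  synthetic = names(formals(syntheticSpec)),
  paths = c("data", "out", "model")
)

#' Read a run configuration file
#'
#' Loads a YAML file with optional sections `model`, `train`, `synthetic` and
#' `paths`, applies CLI-style overrides, and rejects unknown sections or keys
#' so that typos cannot silently fall back to defaults.
#'
#' @param path Path to a YAML file, or `NULL` for all defaults.
#' @param overrides Named list of `section$key` overrides, e.g.
#'   `list(train = list(nEpochs = 5))`.
#' @return List with elements `model` ([modelConfig()]), `train`
#'   ([trainConfig()]), `synthetic` ([syntheticSpec()]) and `paths`.
#' @export
readRunConfig <- function(path = NULL, overrides = list()) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (!is.list(raw)) stopf("run configuration must be a YAML mapping")
  bad <- setdiff(names(raw), names(.runConfigSchema))
  if (length(bad)) stopf("unknown configuration section(s): %s",
                         paste(bad, collapse = ", "))
  for (sec in names(overrides))
    raw[[sec]] <- utils::modifyList(raw[[sec]] %||% list(), overrides[[sec]])
  for (sec in setdiff(names(raw), "paths")) {
    bad <- setdiff(names(raw[[sec]]), .runConfigSchema[[sec]])
    if (length(bad)) stopf("unknown key(s) in section '%s': %s", sec,
                           paste(bad, collapse = ", "))
  }
  list(model = do.call(modelConfig, raw$model %||% list()),
       train = do.call(trainConfig, raw$train %||% list()),
       synthetic = do.call(syntheticSpec, raw$synthetic %||% list()),
       paths = raw$paths %||% list())
}

#' Serialize a resolved run configuration
#'
#' @param config List as returned by [readRunConfig()].
#' @param path Output YAML path.
#' @return `path`, invisibly.
#' @export
writeRunConfig <- function(config, path) {
  strip <- function(x) { x <- unclass(x); x[!vapply(x, is.null, TRUE)] }
  yaml::write_yaml(lapply(config, strip), path)
  invisible(path)
}
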