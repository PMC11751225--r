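# Shared fixtures. Heavy objects (the default synthetic dataset and one
# trained model) are built lazily and cached for the whole test run.

.fixtures <- new.env(parent = emptyenv())

# small architecture for fast unit tests: 96 -> 48 timepoints, 8 channels
smallCfg <- function(...) {
  modelConfig(inputLen = 96L, nFilters = 8L, convKernel = 16L, convPad = 7L,
              seReduction = 2L, ...)
}

# parameter list with every trainable entry zeroed (running stats kept at
# their 0/1 initialization)
zeroParams <- function(cfg) {
  p <- initParams(cfg, seed = 1)
  for (nm in drowsEEG:::trainableNames(p)) p[[nm]][] <- 0
  p
}

# tiny two-subject, linearly separable set: class 1 carries a strong 10 Hz
# tone, class 0 a strong 20 Hz tone
tinySeparableSet <- function(n = 40L, len = 384L, fs = 128, seed = 1L) {
  set.seed(seed)
  t <- (seq_len(len) - 1) / fs
  X <- t(vapply(seq_len(n), function(i) {
    f <- if (i %% 2L) 10 else 20
    sin(2 * pi * f * t + runif(1, 0, 2 * pi)) + 0.3 * rnorm(len)
  }, numeric(len)))
  EpochSet(X, labels = as.integer(seq_len(n) %% 2L),
           subjects = rep(1:2, length.out = n))
}

# the default synthetic study conditions (8 subjects x 200 epochs)
defaultSynthSet <- function() {
  if (is.null(.fixtures$es))
    .fixtures$es <- simulateEpochSet(syntheticSpec(seed = 7L))
  .fixtures$es
}

# one model trained under the default conditions: subjects 2..8 train,
# subject 1 is held out
synthNet <- function() {
  if (is.null(.fixtures$net)) {
    es <- defaultSynthSet()
    .fixtures$net <- trainModel(subsetEpochs(es, subjectIds(es) != 1L),
                                modelConfig(),
                                trainConfig(nEpochs = 10L, seed = 1L))
  }
  .fixtures$net
}

heldOutSet <- function() {
  es <- defaultSynthSet()
  subsetEpochs(es, subjectIds(es) == 1L)
}

# write a miniature deposit-shaped archive (multi-channel, plain text);
# returns its ground truth for validation
makeMiniDeposit <- function(dir, nSubjects = 11L, perSubject = 6L,
                            nChannels = 2L, nSamples = 384L, seed = 3L) {
  set.seed(seed)
  n <- nSubjects * perSubject
  sig <- matrix(rnorm(n * nChannels * nSamples), n)
  # make channel 2 recognizably different from channel 1
  sig[, (nSamples + 1):(2 * nSamples)] <-
    sig[, (nSamples + 1):(2 * nSamples)] + 100
  labels <- rep_len(c(0L, 1L), n)
  subjects <- rep(seq_len(nSubjects), each = perSubject)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  con <- file(file.path(dir, "EEGsample.tsv"), "w")
  for (i in seq_len(n))
    writeLines(paste(sprintf("%.17g", sig[i, ]), collapse = "\t"), con)
  close(con)
  writeLines(as.character(labels), file.path(dir, "substate.tsv"))
  writeLines(as.character(subjects), file.path(dir, "subindex.tsv"))
  jsonlite::write_json(list(nEpochs = n, nChannels = nChannels,
                            nSamples = nSamples, samplingRate = 128),
                       file.path(dir, "meta.json"), auto_unbox = TRUE)
  list(signals = sig, labels = labels, subjects = subjects)
}
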