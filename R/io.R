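# Plain-text archives. Signals are written with "%.17g" so doubles
# round-trip bit-identically.

fmtMatrix <- function(M, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(M)))
    writeLines(paste(sprintf("%.17g", M[i, ]), collapse = "\t"), con)
  invisible(path)
}

scanMatrix <- function(path, n, m) {
  matrix(scan(path, what = double(), quiet = TRUE), n, m, byrow = TRUE)
}

#' Write an EpochSet archive
#'
#' Plain-text directory archive: `signals.tsv` (one epoch per row, full
#' precision), `epochs.tsv` (label, subject), optional `events.tsv`, and a
#' `meta.json` sidecar. Archives round-trip bit-identically through
#' [readEpochSet()].
#'
#' @param x An [EpochSet-class].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeEpochSet <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fmtMatrix(epochSignals(x), file.path(dir, "signals.tsv"))
  utils::write.table(
    data.frame(label = epochLabels(x), subject = subjectIds(x)),
    file.path(dir, "epochs.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  ev <- epochEvents(x)
  if (!is.null(ev))
    utils::write.table(ev, file.path(dir, "events.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(provenance = provenance(x), samplingRate = samplingRate(x),
         nEpochs = ncol(x), nSamples = nrow(x)),
    file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read an EpochSet archive
#'
#' @param dir Directory written by [writeEpochSet()].
#' @return An [EpochSet-class].
#' @export
readEpochSet <- function(dir) {
  metaPath <- file.path(dir, "meta.json")
  if (!file.exists(metaPath)) stopf("no meta.json in '%s'", dir)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  X <- scanMatrix(file.path(dir, "signals.tsv"), meta$nEpochs, meta$nSamples)
  ep <- utils::read.table(file.path(dir, "epochs.tsv"), header = TRUE,
                          sep = "\t")
  evPath <- file.path(dir, "events.tsv")
  ev <- if (file.exists(evPath))
    utils::read.table(evPath, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE) else NULL
  EpochSet(X, ep$label, ep$subject, events = ev,
           provenance = meta$provenance, samplingRate = meta$samplingRate)
}

#' Load a converted public deposit
#'
#' Reads a preprocessed drowsiness deposit that has been converted from its
#' matrix-container distribution into the package's plain-text layout (one
#' `<field>.tsv` per array, see `scripts/convert_deposit.py` in the source
#' repository). The signals array may be multi-channel (epochs x
#' channels*samples, channel-major blocks); `channelIndex` selects the
#' occipital channel. Field names are configuration, not code, so dialect
#' drift in public files cannot break the loader.
#'
#' @param path Directory holding the converted deposit.
#' @param fieldMap Named list mapping the logical fields `signals`, `labels`,
#'   `subjects` to the deposit's array names (defaults follow the public
#'   deposit's conventions).
#' @param channelIndex 1-based channel to extract (the occipital midline
#'   channel index in the deposit's montage; consult its channel list).
#' @param expectedLen Expected epoch length in samples.
#' @return An [EpochSet-class] with provenance `"deposit"`; per-subject class
#'   counts are reported via `message()`.
#' @export
loadDeposit <- function(path,
                        fieldMap = list(signals = "EEGsample",
                                        labels = "substate",
                                        subjects = "subindex"),
                        channelIndex = 1L, expectedLen = 384L) {
  metaPath <- file.path(path, "meta.json")
  if (!file.exists(metaPath))
    stopf("deposit archive '%s' has no meta.json (convert it first)", path)
  meta <- jsonlite::read_json(metaPath, simplifyVector = TRUE)
  files <- lapply(fieldMap, function(f) file.path(path, paste0(f, ".tsv")))
  for (nm in names(files))
    if (!file.exists(files[[nm]]))
      stopf("deposit field '%s' (expected file '%s') is missing",
            nm, basename(files[[nm]]))
  nCh <- meta$nChannels %||% 1L
  if (channelIndex < 1 || channelIndex > nCh)
    stopf("channelIndex %d outside the deposit's %d channels",
          channelIndex, nCh)
  X <- scanMatrix(files$signals, meta$nEpochs, nCh * meta$nSamples)
  cols <- ((channelIndex - 1L) * meta$nSamples + 1L):(channelIndex * meta$nSamples)
  X <- X[, cols, drop = FALSE]
  if (ncol(X) != expectedLen)
    stopf("deposit epochs have %d samples, expected %d", ncol(X), expectedLen)
  labels <- scan(files$labels, what = double(), quiet = TRUE)
  if (!all(labels %in% c(0, 1)))
    stopf("deposit labels outside {0, 1}")
  subjects <- scan(files$subjects, what = double(), quiet = TRUE)
  es <- EpochSet(X, labels, subjects, provenance = "deposit",
                 samplingRate = meta$samplingRate %||% 128)
  tab <- table(subject = subjects, label = labels)
  message(sprintf("loaded %d epochs / %d subjects (alert %d, drowsy %d)",
                  length(labels), nrow(tab), sum(labels == 0),
                  sum(labels == 1)))
  es
}

#' Save a model checkpoint
#'
#' Text checkpoint: `config.json` sidecar (architecture, training history,
#' freeze mask) plus `params.tsv` with every parameter scalar at full
#' precision.
#'
#' @param net A [DrowsyNet-class].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
saveModel <- function(net, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config = unclass(net@config), trained = net@trained,
         history = net@history, freezeMask = net@freezeMask),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  con <- file(file.path(dir, "params.tsv"), "w")
  on.exit(close(con))
  for (nm in names(net@params))
    writeLines(paste(nm, paste(sprintf("%.17g", as.vector(net@params[[nm]])),
                               collapse = "\t"), sep = "\t"), con)
  invisible(dir)
}

#' Load a model checkpoint
#'
#' Validates that every stored array matches the shape implied by the stored
#' configuration.
#'
#' @param dir Directory written by [saveModel()].
#' @return A [DrowsyNet-class].
#' @export
loadModel <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "config.json"),
                              simplifyVector = TRUE)
  cfgArgs <- meta$config[names(meta$config) %in% names(formals(modelConfig))]
  cfg <- do.call(modelConfig, cfgArgs)
  template <- initParams(cfg, seed = 0L)
  lines <- readLines(file.path(dir, "params.tsv"))
  params <- template
  seen <- character(0)
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    nm <- parts[1]
    if (!nm %in% names(template))
      stopf("checkpoint has unknown parameter '%s'", nm)
    vals <- as.numeric(parts[-1])
    if (length(vals) != length(template[[nm]]))
      stopf("checkpoint parameter '%s' has %d values, expected %d",
            nm, length(vals), length(template[[nm]]))
    p <- template[[nm]]
    p[] <- vals
    params[[nm]] <- p
    seen <- c(seen, nm)
  }
  missing <- setdiff(names(template), seen)
  if (length(missing))
    stopf("checkpoint is missing parameter(s): %s",
          paste(missing, collapse = ", "))
  fm <- meta$freezeMask
  if (is.null(dim(fm))) fm <- matrix(numeric(0), 0, 0)
  new("DrowsyNet", config = cfg, params = params,
      freezeMask = matrix(as.numeric(fm), nrow(fm), ncol(fm)),
      history = as.numeric(meta$history %||% numeric(0)),
      trained = isTRUE(meta$trained))
}
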