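#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

setOldClass(c("modelConfig", "list"))
setOldClass(c("trainConfig", "list"))
setOldClass(c("syntheticSpec", "list"))

#' EpochSet: labeled single-channel EEG epochs
#'
#' An `EpochSet` holds a collection of fixed-length single-channel EEG epochs
#' together with their binary state labels (0 = alert, 1 = drowsy) and subject
#' identifiers. It extends [SummarizedExperiment::SummarizedExperiment]: the
#' `"signal"` assay stores epochs column-wise (timepoints x epochs), `colData`
#' carries `label` and `subject`, and synthetic sets additionally record their
#' ground-truth oscillatory events (one row per injected event) in
#' `metadata(x)$events`.
#'
#' @slot provenance Either `"synthetic"` or `"deposit"`.
#' @slot samplingRate Sampling rate in Hz.
#'
#' @seealso [EpochSet()] for construction, [simulateEpochSet()] for the
#'   synthetic generator, [readEpochSet()]/[writeEpochSet()] for on-disk
#'   archives.
#' @export
setClass("EpochSet",
  contains = "SummarizedExperiment",
  representation(provenance = "character", samplingRate = "numeric")
)

setValidity("EpochSet", function(object) {
  msg <- character()
  if (!"signal" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'signal' is missing")
  cd <- colData(object)
  for (f in c("label", "subject"))
    if (!f %in% colnames(cd)) msg <- c(msg, sprintf("colData field '%s' is missing", f))
  if ("label" %in% colnames(cd) && !all(cd$label %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0 (alert) or 1 (drowsy)")
  if (!object@provenance %in% c("synthetic", "deposit"))
    msg <- c(msg, "provenance must be 'synthetic' or 'deposit'")
  ev <- metadata(object)$events
  if (!is.null(ev)) {
    need <- c("epoch", "start", "end", "kind")
    if (!all(need %in% names(ev))) {
      msg <- c(msg, "events table needs columns epoch, start, end, kind")
    } else if (nrow(ev)) {
      L <- nrow(object)
      if (any(ev$start < 1L) || any(ev$end > L) || any(ev$end <= ev$start))
        msg <- c(msg, "event intervals must be non-degenerate and lie within the epoch")
      if (any(ev$epoch < 1L) || any(ev$epoch > ncol(object)))
        msg <- c(msg, "event epoch indices out of range")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct an EpochSet
#'
#' @param signals Numeric matrix of epochs in rows (n x L, e.g. n x 384).
#' @param labels Integer vector of per-epoch labels, 0 = alert, 1 = drowsy.
#' @param subjects Integer (or factor-like) vector of subject identifiers.
#' @param events Optional data.frame of ground-truth events with columns
#'   `epoch` (1-based epoch index), `start`, `end` (1-based sample indices,
#'   `end` inclusive) and `kind` (one of `"theta_delta"`, `"alpha_spindle"`,
#'   `"beta"`, `"blink"`).
#' @param provenance `"synthetic"` or `"deposit"`.
#' @param samplingRate Sampling rate in Hz (default 128).
#' @return An [EpochSet-class] object.
#' @examples
#' es <- EpochSet(matrix(rnorm(10 * 384), 10), rep(0:1, 5), rep(1:2, each = 5))
#' es
#' @export
EpochSet <- function(signals, labels, subjects, events = NULL,
                     provenance = c("synthetic", "deposit"),
                     samplingRate = 128) {
  provenance <- match.arg(provenance)
  signals <- as.matrix(signals)
  n <- nrow(signals)
  if (length(labels) != n || length(subjects) != n)
    stopf("signals (%d epochs), labels (%d) and subjects (%d) disagree in length",
          n, length(labels), length(subjects))
  se <- SummarizedExperiment(
    assays = list(signal = t(signals)),
    colData = DataFrame(label = as.integer(labels), subject = as.integer(subjects))
  )
  obj <- new("EpochSet", se, provenance = provenance, samplingRate = samplingRate)
  if (!is.null(events)) metadata(obj)$events <- as.data.frame(events)
  validObject(obj)
  obj
}

#' @describeIn EpochSet Epoch signals as an epochs-in-rows matrix (n x L).
#' @param x,object An `EpochSet`.
#' @export
epochSignals <- function(x) t(assay(x, "signal"))

#' @describeIn EpochSet Integer label vector (0 alert / 1 drowsy).
#' @export
epochLabels <- function(x) colData(x)$label

#' @describeIn EpochSet Integer subject identifier vector.
#' @export
subjectIds <- function(x) colData(x)$subject

#' @describeIn EpochSet Ground-truth event table (`NULL` when absent).
#' @export
epochEvents <- function(x) metadata(x)$events

#' @describeIn EpochSet Provenance string.
#' @export
provenance <- function(x) x@provenance

#' @describeIn EpochSet Sampling rate in Hz.
#' @export
samplingRate <- function(x) x@samplingRate

#' Subset an EpochSet by epoch index
#'
#' Keeps labels, subjects and the event table consistent with the retained
#' epochs (event epoch indices are remapped).
#' @param x An `EpochSet`.
#' @param idx Integer or logical index over epochs.
#' @return An `EpochSet` with the selected epochs, in the requested order.
#' @export
subsetEpochs <- function(x, idx) {
  idx <- seq_len(ncol(x))[idx]
  out <- x[, idx]
  ev <- metadata(x)$events
  if (!is.null(ev) && nrow(ev)) {
    keep <- ev$epoch %in% idx
    ev <- ev[keep, , drop = FALSE]
    ev$epoch <- match(ev$epoch, idx)
    metadata(out)$events <- ev[order(ev$epoch, ev$start), , drop = FALSE]
  }
  out
}

setMethod("show", "EpochSet", function(object) {
  lab <- epochLabels(object)
  cat(sprintf("EpochSet: %d epochs x %d samples at %g Hz (%s)\n",
              ncol(object), nrow(object), object@samplingRate, object@provenance))
  cat(sprintf("  subjects: %d | alert: %d | drowsy: %d\n",
              length(unique(subjectIds(object))), sum(lab == 0L), sum(lab == 1L)))
  ev <- metadata(object)$events
  if (!is.null(ev)) cat(sprintf("  annotated events: %d\n", nrow(ev)))
  invisible(NULL)
})

#' DrowsyNet: a trained (or initialized) residual shrinkage network
#'
#' Bundles the architectural configuration, the parameter list, the random
#' weight-freezing mask applied to the classification head, and the training
#' loss history.
#'
#' @slot config Model configuration list from [modelConfig()].
#' @slot params Named list of parameter arrays (see [initParams()]).
#' @slot freezeMask Binary matrix, 1 = trainable head weight, 0 = frozen;
#'   `NULL`-like (0 x 0) before training.
#' @slot history Numeric vector of mean training loss per epoch.
#' @slot trained Logical flag.
#' @export
setClass("DrowsyNet", representation(
  config = "list", params = "list", freezeMask = "matrix",
  history = "numeric", trained = "logical"
))

setMethod("show", "DrowsyNet", function(object) {
  cfg <- object@config
  cat(sprintf("DrowsyNet (%s thresholds): %d filters, kernel %d, input %d -> %d\n",
              cfg$thresholdMode, cfg$nFilters, cfg$convKernel,
              cfg$inputLen, outputLen(cfg)))
  cat(sprintf("  trainable parameters: %d | trained: %s\n",
              countParameters(cfg), object@trained))
  if (length(object@history))
    cat(sprintf("  final training loss: %.4f (%d epochs)\n",
                utils::tail(object@history, 1), length(object@history)))
  invisible(NULL)
})
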