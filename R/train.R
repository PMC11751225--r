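#' Random weight-freezing mask
#'
#' Draws a matrix `K` of uniform `[0, 1]` variates with the shape of the head
#' weight matrix and binarizes it at threshold `t`: entries with `K < t` are
#' frozen (mask 0) and are never updated during training, the rest stay
#' trainable (mask 1). The expected frozen fraction is `t`. The mask is drawn
#' once per training run; the head bias is never masked.
#'
#' @param dim Integer vector, the head weight matrix dimensions.
#' @param t Freeze threshold in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return List of class `"freezeMask"` with `kRaw` (the uniform draws) and
#'   `mask` (binary; 1 = trainable, 0 = frozen).
#' @examples
#' fm <- makeFreezeMask(c(32, 2), t = 0.2, seed = 1)
#' mean(fm$mask == 0)  # about 0.2
#' @export
makeFreezeMask <- function(dim, t, seed = NULL) {
  if (t < 0 || t > 1) stopf("freeze threshold t must lie in [0, 1]")
  kRaw <- withSeed(seed, matrix(runif(prod(dim)), dim[1], dim[2]))
  structure(list(kRaw = kRaw, mask = (kRaw >= t) * 1), class = "freezeMask")
}

#' Label-smoothed cross-entropy loss
#'
#' `Loss = -sum_c [ 1{c==y} (1 - alpha) + alpha / C ] log p_c`. With
#' `alpha = 0` this is the ordinary cross entropy; the uniform prediction
#' always costs `log(C)`.
#'
#' @param p Probability vector over the `C` classes (clipped at 1e-12).
#' @param y True class index, 0-based (0 = alert, 1 = drowsy).
#' @param alpha Smoothing parameter in `[0, 1)`.
#' @param C Number of classes.
#' @return Nonnegative scalar loss.
#' @examples
#' labelSmoothedLoss(c(0.9, 0.1), 0, alpha = 0.1)  # 0.2152
#' @export
labelSmoothedLoss <- function(p, y, alpha = 0.1, C = length(p)) {
  if (length(y) != 1 || !y %in% (seq_len(C) - 1L))
    stopf("invalid class index y = %s for C = %d classes", toString(y), C)
  q <- rep(alpha / C, C)
  q[y + 1L] <- q[y + 1L] + (1 - alpha)
  -sum(q * log(pmax(p, 1e-12)))
}

# smoothed target matrix for a label vector (0-based labels)
smoothTargets <- function(y, alpha, C) {
  q <- matrix(alpha / C, length(y), C)
  q[cbind(seq_along(y), y + 1L)] <- alpha / C + (1 - alpha)
  q
}

adamInit <- function(params, nms) {
  zero <- function(x) { x[] <- 0; x }
  list(m = lapply(params[nms], zero), v = lapply(params[nms], zero), t = 0L)
}

adamStep <- function(params, grads, state, lr, b1 = 0.9, b2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - b1^state$t
  c2 <- 1 - b2^state$t
  for (nm in names(state$m)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

#' Train the residual shrinkage network
#'
#' Mini-batch Adam optimization of the label-smoothed cross entropy. The
#' gradient of the head weight matrix is multiplied elementwise by the binary
#' freeze mask before every update, so frozen entries are bit-identical
#' before and after training. Initialization, the freeze mask, batch
#' shuffling and dropout are all driven by `train$seed`, making a run
#' reproducible.
#'
#' @param trainSet An [EpochSet-class] with both classes present.
#' @param model A [modelConfig()].
#' @param train A [trainConfig()].
#' @param verbose Print per-epoch mean loss.
#' @return A [DrowsyNet-class] object.
#' @export
trainModel <- function(trainSet, model = modelConfig(), train = trainConfig(),
                       verbose = FALSE) {
  X <- epochSignals(trainSet)
  y <- epochLabels(trainSet)
  if (nrow(X) == 0) stopf("empty training set")
  if (length(unique(y)) < 2)
    stopf("degenerate training set: both classes must be present")
  withSeed(train$seed, {
    params <- initParams(model)
    fm <- makeFreezeMask(dim(params$head_w), train$freezeThreshold)
    res <- cppTrain(X, as.integer(y), params, model, train, fm$mask)
    if (verbose)
      for (ep in seq_along(res$history))
        message(sprintf("epoch %d: loss %.4f", ep, res$history[ep]))
    new("DrowsyNet", config = model, params = res$params,
        freezeMask = fm$mask, history = as.numeric(res$history),
        trained = TRUE)
  })
}

#' Predict class probabilities
#'
#' Evaluation-mode forward pass (running batch-norm statistics, no dropout),
#' chunked for memory.
#'
#' @param net A [DrowsyNet-class].
#' @param x An [EpochSet-class] or an epochs-in-rows matrix.
#' @param chunk Number of epochs per forward chunk.
#' @return Probability matrix, one row per epoch, columns alert/drowsy.
#' @export
predictProbs <- function(net, x, chunk = 512L) {
  X <- if (is(x, "EpochSet")) epochSignals(x) else as.matrix(x)
  out <- matrix(NA_real_, nrow(X), net@config$nClasses)
  for (s in seq(1L, nrow(X), by = chunk)) {
    i <- s:min(s + chunk - 1L, nrow(X))
    out[i, ] <- cppForward(X[i, , drop = FALSE], net@params, net@config,
                           training = FALSE, trace = FALSE)$probs
  }
  out
}

#' Evaluate a trained model on a test set
#'
#' Argmax-probability predictions scored by accuracy and the F1 score of the
#' drowsy class (`F1 = 2PR / (P + R)`, 0 when precision and recall are both
#' undefined or zero).
#'
#' @param net A [DrowsyNet-class].
#' @param testSet An [EpochSet-class].
#' @return List with `confusion` (2 x 2, rows = true alert/drowsy, columns =
#'   predicted), `accuracy` (percent), `f1` (percent, drowsy positive),
#'   `predictions` (0/1 vector) and `n`.
#' @export
evaluateModel <- function(net, testSet) {
  if (ncol(testSet) == 0) stopf("empty test set")
  probs <- predictProbs(net, testSet)
  pred <- max.col(probs, ties.method = "first") - 1L
  out <- scorePredictions(epochLabels(testSet), pred)
  out$predictions <- pred
  out
}

# confusion matrix, accuracy (%) and drowsy-class F1 (%) with zero-division
# guards; shared by evaluateModel and the fold reports
scorePredictions <- function(y, pred) {
  cm <- table(factor(y, 0:1), factor(pred, 0:1))
  cm <- matrix(as.integer(cm), 2, 2,
               dimnames = list(true = c("alert", "drowsy"),
                               pred = c("alert", "drowsy")))
  tp <- cm[2, 2]; fp <- cm[1, 2]; fn <- cm[2, 1]
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  list(confusion = cm, accuracy = 100 * sum(diag(cm)) / sum(cm),
       f1 = 100 * f1, n = length(y))
}

#' Leave-one-subject-out cross-validation
#'
#' One fold per subject (per repeat): the held-out subject's epochs from
#' `testPool` form the test set and all other subjects' epochs from
#' `trainPool` form the training set. Passing distinct pools mirrors training
#' on a balanced set while testing on each subject's unbalanced recordings; a
#' single pool gives the plain protocol. Fold partition correctness
#' (disjointness, coverage, subject exclusion) is asserted on every run.
#'
#' @param trainPool An [EpochSet-class] grouped by subject.
#' @param testPool Optional second [EpochSet-class] with the identical subject
#'   set; defaults to `trainPool`.
#' @param model A [modelConfig()].
#' @param train A [trainConfig()]; each fold re-seeds initialization and the
#'   freeze mask deterministically from `train$seed`.
#' @param nRepeats Number of repeats over all subjects (fresh seeds each).
#' @param verbose Print per-fold metrics.
#' @return List with `folds` (data.frame: repeat, subject, n, accuracy, f1),
#'   `confusions` (per-fold matrices), `histories` (per-fold loss vectors) and
#'   `summary` (`meanAccuracy`, `meanF1` in percent, averaged over folds).
#' @export
losoCV <- function(trainPool, testPool = NULL, model = modelConfig(),
                   train = trainConfig(), nRepeats = 1L, verbose = FALSE) {
  if (is.null(testPool)) testPool <- trainPool
  subjects <- sort(unique(subjectIds(trainPool)))
  if (!identical(subjects, sort(unique(subjectIds(testPool)))))
    stopf("protocol error: train and test pools must cover the same subjects")
  if (length(subjects) < 2) stopf("LOSO needs at least 2 subjects")
  folds <- list()
  confusions <- list()
  histories <- list()
  k <- 0L
  for (r in seq_len(nRepeats)) {
    for (s in subjects) {
      k <- k + 1L
      trIdx <- subjectIds(trainPool) != s
      teIdx <- subjectIds(testPool) == s
      stopifnot(!any(subjectIds(trainPool)[trIdx] == s), any(teIdx))
      tc <- train
      tc$seed <- train$seed + 997L * (r - 1L) + match(s, subjects)
      net <- trainModel(subsetEpochs(trainPool, trIdx), model, tc)
      ev <- evaluateModel(net, subsetEpochs(testPool, teIdx))
      folds[[k]] <- data.frame(rep = r, subject = s, n = ev$n,
                               accuracy = ev$accuracy, f1 = ev$f1)
      confusions[[k]] <- ev$confusion
      histories[[k]] <- net@history
      if (verbose)
        message(sprintf("fold %d (subject %d, rep %d): acc %.1f%% f1 %.1f%%",
                        k, s, r, ev$accuracy, ev$f1))
    }
  }
  folds <- do.call(rbind, folds)
  # partition check: test folds of one repeat tile the test pool exactly
  stopifnot(sum(folds$n[folds$rep == 1]) == ncol(testPool))
  list(folds = folds, confusions = confusions, histories = histories,
       summary = list(meanAccuracy = mean(folds$accuracy),
                      meanF1 = mean(folds$f1)))
}
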