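# Network engine. Batched activations are stored as (n*T) x C matrices with
# rows ordered sample-fastest (row = s + (p-1)*n for sample s, timepoint p),
# so per-channel batch norm is column-wise and per-sample temporal reductions
# are a single rowsum() over grp = rep(1:n, T). All heavy steps are BLAS
# matrix products.

.bnEps <- 1e-5
.bnMomentum <- 0.1

# column indices into the zero-padded input for the im2col unfolding
im2colIndex <- function(config) {
  K <- config$convKernel
  T <- outputLen(config)
  outer(seq_len(K), (seq_len(T) - 1L) * config$convStride, `+`)
}

addBias <- function(M, b) M + rep(b, each = nrow(M))

bnForward <- function(A, g, b, rm, rv, training) {
  m <- nrow(A)
  if (training) {
    mu <- colMeans(A)
    v <- pmax(colMeans(A * A) - mu * mu, 0)
    rmNew <- (1 - .bnMomentum) * rm + .bnMomentum * mu
    rvNew <- (1 - .bnMomentum) * rv +
      .bnMomentum * v * if (m > 1) m / (m - 1) else 1
  } else {
    mu <- rm; v <- rv; rmNew <- rm; rvNew <- rv
  }
  invstd <- 1 / sqrt(v + .bnEps)
  xhat <- (A - rep(mu, each = m)) * rep(invstd, each = m)
  list(out = xhat * rep(g, each = m) + rep(b, each = m),
       xhat = xhat, invstd = invstd, g = g, rm = rmNew, rv = rvNew)
}

bnBackward <- function(dY, cache, training) {
  m <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(cache$g, each = m)
  if (!training) {
    dA <- dxhat * rep(cache$invstd, each = m)
  } else {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * cache$xhat)
    dA <- rep(cache$invstd / m, each = m) *
      (m * dxhat - rep(s1, each = m) - cache$xhat * rep(s2, each = m))
  }
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

#' Soft thresholding
#'
#' The shrinkage operator at the heart of the residual shrinkage unit: values
#' inside the dead zone `[-tau, tau]` become exactly zero, values outside are
#' shrunk toward zero by `tau`:
#' `y = x - tau` for `x > tau`, `0` for `|x| <= tau`, `x + tau` for `x < -tau`.
#'
#' @param x Numeric vector, or a channels-by-time matrix.
#' @param tau Nonnegative threshold; a scalar, or one value per channel (row)
#'   when `x` is a matrix.
#' @return Shrunk array with the shape of `x`.
#' @examples
#' softThreshold(c(2, 0.3, -2), 0.5)  # 1.5 0 -1.5
#' @export
softThreshold <- function(x, tau) {
  if (any(tau < 0)) stopf("invalid threshold: tau must be nonnegative")
  if (is.matrix(x) && length(tau) > 1 && length(tau) != nrow(x))
    stopf("tau must be scalar or one value per channel (row) of x")
  sign(x) * pmax(abs(x) - tau, 0)
}

# squeeze-and-excitation threshold branch on an (n*T) x C batch;
# a = per-sample temporal mean of |U| (n x C)
seBranchForward <- function(a, params, mode, training) {
  s1 <- addBias(a %*% params$se1_w, params$se1_b)
  bnse <- bnForward(s1, params$sebn_g, params$sebn_b,
                    params$sebn_rm, params$sebn_rv, training)
  z1 <- pmax(bnse$out, 0)
  s2 <- addBias(z1 %*% params$se2_w, params$se2_b)
  sig <- 1 / (1 + exp(-s2))
  tau <- if (mode == "CW") sig * a else sig * rowMeans(a)
  list(s1 = s1, bnse = bnse, z1 = z1, s2 = s2, sigma = sig, tau = tau)
}

#' Learned soft thresholds from the attention branch
#'
#' Computes the squeeze-and-excitation scaling factors and the resulting soft
#' thresholds for a feature map: the absolute feature map is averaged over
#' time, passed through a bottleneck (dense reduce, batch norm, rectifier,
#' dense restore) and a logistic squashing, giving per-channel scaling factors
#' `sigma` in (0, 1); the threshold is `tau_r = sigma_r * mean_i |U[r, i]|`
#' per channel (`"CW"`) or `tau = sigma * mean |U|` shared across channels
#' (`"CS"`). By construction `0 <= tau_r <= mean_i |U[r, i]|`, which keeps
#' shrinkage from zeroing entire channels.
#'
#' @param U Feature map, channels x time.
#' @param params Parameter list holding the `se*`/`sebn*` entries
#'   (see [initParams()]); batch norm uses its running statistics.
#' @param mode `"CW"` (per-channel) or `"CS"` (shared).
#' @return List with `sigma` (scaling factors) and `tau` (thresholds); both
#'   length `nrow(U)` for `"CW"`, scalars for `"CS"`.
#' @export
seThresholds <- function(U, params, mode = c("CW", "CS")) {
  mode <- match.arg(mode)
  if (!all(is.finite(U))) stopf("non-finite values in feature map U")
  a <- matrix(rowMeans(abs(U)), nrow = 1)
  se <- seBranchForward(a, params, mode, training = FALSE)
  list(sigma = as.vector(se$sigma), tau = as.vector(se$tau))
}

# full batched forward pass; X is n x inputLen
forwardBatch <- function(X, params, config, training = FALSE) {
  n <- nrow(X)
  K <- config$convKernel; C <- config$nFilters
  T <- outputLen(config); pad <- config$convPad
  if (ncol(X) != config$inputLen)
    stopf("epoch length %d does not match config inputLen %d",
          ncol(X), config$inputLen)
  if (!all(is.finite(X))) stopf("non-finite values in input")
  grp <- rep(seq_len(n), times = T)

  Xp <- cbind(matrix(0, n, pad), X, matrix(0, n, pad))
  idx <- im2colIndex(config)
  Xcol <- matrix(aperm(array(Xp[, as.vector(idx), drop = FALSE],
                             c(n, K, T)), c(1L, 3L, 2L)), n * T, K)
  H0 <- addBias(Xcol %*% params$conv_w, params$conv_b)
  bn1 <- bnForward(H0, params$bn1_g, params$bn1_b,
                   params$bn1_rm, params$bn1_rv, training)
  S <- softThreshold(bn1$out, config$softshrinkLambda)
  if (training && config$dropoutP > 0) {
    dropMask <- matrix((runif(length(S)) >= config$dropoutP) /
                         (1 - config$dropoutP), nrow(S), ncol(S))
    I <- S * dropMask
  } else {
    dropMask <- NULL
    I <- S
  }

  bn2 <- bnForward(I, params$bn2_g, params$bn2_b,
                   params$bn2_rm, params$bn2_rv, training)
  Z1 <- pmax(bn2$out, 0)
  U1 <- addBias(Z1 %*% params$conv1_w, params$conv1_b)
  bn3 <- bnForward(U1, params$bn3_g, params$bn3_b,
                   params$bn3_rm, params$bn3_rv, training)
  Z2 <- pmax(bn3$out, 0)
  U <- addBias(Z2 %*% params$conv2_w, params$conv2_b)

  a <- rowsum(abs(U), grp) / T
  se <- seBranchForward(a, params, config$thresholdMode, training)
  tauFull <- if (config$thresholdMode == "CW")
    se$tau[grp, , drop = FALSE] else matrix(se$tau[grp], n * T, C)
  O <- sign(U) * pmax(abs(U) - tauFull, 0)
  P <- I + O

  g <- rowsum(P, grp) / T
  logits <- addBias(g %*% params$head_w, params$head_b)
  zmax <- apply(logits, 1, max)
  e <- exp(logits - zmax)
  probs <- e / rowSums(e)

  list(n = n, T = T, grp = grp, training = training,
       Xcol = Xcol, bn1 = bn1, S = S, dropMask = dropMask, I = I,
       bn2 = bn2, Z1 = Z1, bn3 = bn3, Z2 = Z2, U = U, a = a, se = se,
       tauFull = tauFull, O = O, P = P, g = g, logits = logits, probs = probs)
}

# gradient of every trainable parameter given dLoss/dLogits
backwardBatch <- function(fw, params, config, dLogits) {
  n <- fw$n; T <- fw$T; C <- config$nFilters
  grp <- fw$grp; training <- fw$training

  gr <- list(head_w = t(fw$g) %*% dLogits, head_b = colSums(dLogits))
  dg <- dLogits %*% t(params$head_w)
  dP <- dg[grp, , drop = FALSE] / T

  dI <- dP
  M <- abs(fw$U) > fw$tauFull
  dU <- dP * M
  dtauFull <- -(sign(fw$U) * M) * dP
  if (config$thresholdMode == "CW") {
    dtau <- rowsum(dtauFull, grp)
    dsig <- dtau * fw$a
    da <- dtau * fw$se$sigma
  } else {
    dtauS <- rowSums(rowsum(dtauFull, grp))
    dsig <- matrix(dtauS * rowMeans(fw$a), n, 1)
    da <- matrix(dtauS * fw$se$sigma[, 1] / C, n, C)
  }
  ds2 <- dsig * fw$se$sigma * (1 - fw$se$sigma)
  dz1 <- ds2 %*% t(params$se2_w)
  gr$se2_w <- t(fw$se$z1) %*% ds2
  gr$se2_b <- colSums(ds2)
  dbnse <- dz1 * (fw$se$bnse$out > 0)
  bb <- bnBackward(dbnse, fw$se$bnse, training)
  gr$sebn_g <- bb$dgamma; gr$sebn_b <- bb$dbeta
  da <- da + bb$dA %*% t(params$se1_w)
  gr$se1_w <- t(fw$a) %*% bb$dA
  gr$se1_b <- colSums(bb$dA)
  dU <- dU + sign(fw$U) * (da[grp, , drop = FALSE] / T)

  dZ2 <- dU %*% t(params$conv2_w)
  gr$conv2_w <- t(fw$Z2) %*% dU
  gr$conv2_b <- colSums(dU)
  dbn3 <- dZ2 * (fw$bn3$out > 0)
  bb <- bnBackward(dbn3, fw$bn3, training)
  gr$bn3_g <- bb$dgamma; gr$bn3_b <- bb$dbeta
  dU1 <- bb$dA
  dZ1 <- dU1 %*% t(params$conv1_w)
  gr$conv1_w <- t(fw$Z1) %*% dU1
  gr$conv1_b <- colSums(dU1)
  dbn2 <- dZ1 * (fw$bn2$out > 0)
  bb <- bnBackward(dbn2, fw$bn2, training)
  gr$bn2_g <- bb$dgamma; gr$bn2_b <- bb$dbeta
  dI <- dI + bb$dA

  if (!is.null(fw$dropMask)) dI <- dI * fw$dropMask
  dS <- dI * (abs(fw$bn1$out) > config$softshrinkLambda)
  bb <- bnBackward(dS, fw$bn1, training)
  gr$bn1_g <- bb$dgamma; gr$bn1_b <- bb$dbeta
  gr$conv_w <- t(fw$Xcol) %*% bb$dA
  gr$conv_b <- colSums(bb$dA)
  gr
}

# fold freshly computed batch statistics back into the parameter list
updateRunningStats <- function(params, fw) {
  params$bn1_rm <- fw$bn1$rm; params$bn1_rv <- fw$bn1$rv
  params$bn2_rm <- fw$bn2$rm; params$bn2_rv <- fw$bn2$rv
  params$bn3_rm <- fw$bn3$rm; params$bn3_rv <- fw$bn3$rv
  params$sebn_rm <- fw$se$bnse$rm; params$sebn_rv <- fw$se$bnse$rv
  params
}

#' Initialize model parameters
#'
#' Weights use He-uniform initialization (`U(-1/sqrt(fan_in), 1/sqrt(fan_in))`
#' for weights and biases); batch-norm scale/shift start at 1/0 with running
#' mean 0 and running variance 1.
#'
#' @param config A [modelConfig()].
#' @param seed Optional integer seed; the caller's RNG stream is untouched.
#' @return Named list of parameter arrays. Entries suffixed `_rm`/`_rv` are
#'   batch-norm running statistics and are not trainable.
#' @export
initParams <- function(config, seed = NULL) {
  C <- config$nFilters; K <- config$convKernel
  R <- C %/% config$seReduction
  Cout <- if (config$thresholdMode == "CW") C else 1L
  heu <- function(nr, nc, fanIn) {
    b <- 1 / sqrt(fanIn)
    matrix(runif(nr * nc, -b, b), nr, nc)
  }
  withSeed(seed, {
    p <- list(
      conv_w = heu(K, C, K), conv_b = runif(C, -1, 1) / sqrt(K),
      bn1_g = rep(1, C), bn1_b = rep(0, C), bn1_rm = rep(0, C), bn1_rv = rep(1, C),
      bn2_g = rep(1, C), bn2_b = rep(0, C), bn2_rm = rep(0, C), bn2_rv = rep(1, C),
      conv1_w = heu(C, C, C), conv1_b = runif(C, -1, 1) / sqrt(C),
      bn3_g = rep(1, C), bn3_b = rep(0, C), bn3_rm = rep(0, C), bn3_rv = rep(1, C),
      conv2_w = heu(C, C, C), conv2_b = runif(C, -1, 1) / sqrt(C),
      se1_w = heu(C, R, C), se1_b = runif(R, -1, 1) / sqrt(C),
      sebn_g = rep(1, R), sebn_b = rep(0, R), sebn_rm = rep(0, R), sebn_rv = rep(1, R),
      se2_w = heu(R, Cout, R), se2_b = runif(Cout, -1, 1) / sqrt(R),
      head_w = heu(C, config$nClasses, C),
      head_b = runif(config$nClasses, -1, 1) / sqrt(C)
    )
    p
  })
}

trainableNames <- function(params)
  grep("_(rm|rv)$", names(params), invert = TRUE, value = TRUE)

#' Count trainable parameters
#'
#' Exact count of trainable scalars (convolution weights and biases,
#' batch-norm scales and shifts, the squeeze-and-excitation dense layers with
#' their inner batch norm, and the classification head); batch-norm running
#' statistics are excluded. With the default per-channel configuration the
#' total is 5554 (~5.6K).
#'
#' @param config A [modelConfig()].
#' @return Integer count with a `"breakdown"` attribute listing the per-block
#'   subtotals (`basefe`, `rsbu`, `se`, `head`).
#' @export
countParameters <- function(config) {
  C <- config$nFilters; K <- config$convKernel
  R <- C %/% config$seReduction
  Cout <- if (config$thresholdMode == "CW") C else 1L
  basefe <- K * C + C + 2L * C
  rsbu <- 2L * C + (C * C + C) + 2L * C + (C * C + C)
  se <- (C * R + R) + 2L * R + (R * Cout + Cout)
  head <- C * config$nClasses + config$nClasses
  total <- basefe + rsbu + se + head
  attr(total, "breakdown") <- list(basefe = basefe, rsbu = rsbu,
                                   se = se, head = head)
  total
}

#' Base feature extractor forward pass
#'
#' Stride-2 convolution with symmetric zero padding, batch normalization,
#' soft-shrink activation and (in training mode) dropout. A 384-sample epoch
#' yields a 32 x 192 feature map under the default configuration.
#'
#' @param epoch Numeric vector of length `config$inputLen`.
#' @param config A [modelConfig()].
#' @param params Parameter list from [initParams()].
#' @param training Logical; batch statistics and dropout are used only when
#'   `TRUE`.
#' @return Feature map `I`, channels x time.
#' @export
baseFeForward <- function(epoch, config, params, training = FALSE) {
  tr <- modelForward(epoch, config, params, training)
  tr$I
}

#' Residual shrinkage unit forward pass
#'
#' Two pointwise (1x1) convolutions in pre-activation order (batch norm,
#' rectifier, convolution) produce `U`; the attention branch derives the soft
#' thresholds; `O = softThreshold(U, tau)`; the identity shortcut gives
#' `P = I + O`.
#'
#' @param I Input feature map, channels x time.
#' @param config A [modelConfig()].
#' @param params Parameter list.
#' @param training Logical (see [baseFeForward()]).
#' @return List with `U`, `sigma`, `tau`, `O`, `P` (maps channels x time).
#' @export
rsbuForward <- function(I, config, params, training = FALSE) {
  C <- config$nFilters
  if (nrow(I) != C) stopf("feature map has %d channels, config expects %d",
                          nrow(I), C)
  T <- ncol(I)
  A <- t(I)  # rows = time (single sample), cols = channels
  grp <- rep(1L, T)
  bn2 <- bnForward(A, params$bn2_g, params$bn2_b,
                   params$bn2_rm, params$bn2_rv, training)
  Z1 <- pmax(bn2$out, 0)
  U1 <- addBias(Z1 %*% params$conv1_w, params$conv1_b)
  bn3 <- bnForward(U1, params$bn3_g, params$bn3_b,
                   params$bn3_rm, params$bn3_rv, training)
  Z2 <- pmax(bn3$out, 0)
  U <- addBias(Z2 %*% params$conv2_w, params$conv2_b)
  a <- rowsum(abs(U), grp) / T
  se <- seBranchForward(a, params, config$thresholdMode, training = FALSE)
  tauFull <- if (config$thresholdMode == "CW")
    se$tau[grp, , drop = FALSE] else matrix(se$tau[grp], T, C)
  O <- sign(U) * pmax(abs(U) - tauFull, 0)
  P <- A + O
  strip <- function(m) { dimnames(m) <- NULL; m }
  list(U = strip(t(U)), sigma = as.vector(se$sigma), tau = as.vector(se$tau),
       O = strip(t(O)), P = strip(t(P)))
}

#' Full forward pass with intermediate-activation capture
#'
#' Composes the base feature extractor, the residual shrinkage unit, temporal
#' global average pooling and the affine classification head with a softmax.
#' Every intermediate needed by the class-activation interpretation is kept.
#'
#' @param epoch Numeric vector of length `config$inputLen`.
#' @param config A [modelConfig()].
#' @param params Parameter list.
#' @param training Logical; evaluation mode (`FALSE`) is deterministic.
#' @return A `forwardTrace` list: `input`, `I`, `U`, `sigma`, `tau`, `O`,
#'   `P` (the residual output `h`, channels x time), `gap` (length
#'   `nFilters`), `logits` and `probs` (length `nClasses`).
#' @export
modelForward <- function(epoch, config, params, training = FALSE) {
  epoch <- as.numeric(epoch)
  fw <- cppForward(matrix(epoch, 1), params, config, training = training,
                   trace = TRUE)
  # n = 1: batched rows are timepoints, so t() yields channels x time
  trace <- list(
    input = epoch,
    I = t(fw$I), U = t(fw$U),
    sigma = as.vector(fw$sigma), tau = as.vector(fw$tau),
    O = t(fw$O), P = t(fw$P),
    gap = as.vector(fw$g), logits = as.vector(fw$logits),
    probs = as.vector(fw$probs)
  )
  class(trace) <- c("forwardTrace", "list")
  trace
}
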