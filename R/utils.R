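#' @importFrom stats rnorm runif fft sd cor rbinom rlnorm
#' @importFrom methods new validObject is
#' @importFrom Rcpp evalCpp
#' @useDynLib drowsEEG, .registration = TRUE
NULL

# Evaluate expr under a temporary RNG state seeded with `seed`; the caller's
# stream is restored afterwards. seed = NULL uses the current stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Root-mean-square of a numeric vector.
rmsValue <- function(x) sqrt(mean(x^2))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
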