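#' @useDynLib sflimfret, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm pt rpois optim convolve fft sd var
#' @importFrom utils head tail
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a fixed RNG seed
#'
#' All stochastic operations in the package funnel through this helper so
#' that every simulation is a pure function of its seed: the global RNG
#' state is saved, the seed applied, and the previous state restored on
#' exit.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  withr::with_seed(as.integer(seed), expr)
}

## Derive k reproducible sub-seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

stop_sflim <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "sflim_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

## Sum adjacent groups of `factor` columns of a matrix (TCSPC rebinning).
rebin_columns <- function(m, factor) {
  factor <- as.integer(factor)
  if (factor == 1L) return(m)
  n <- nrow(m)
  k <- ncol(m)
  if (k %% factor != 0L)
    stop_sflim(sprintf("number of bins (%d) not divisible by rebin factor %d",
                       k, factor), "sflim_dimension_error")
  kk <- k %/% factor
  a <- array(m, dim = c(n, factor, kk))
  out <- matrix(0, n, kk)
  for (s in seq_len(factor)) out <- out + matrix(a[, s, ], n, kk)
  out
}

## Sum adjacent groups of length `factor` in a vector.
rebin_vector <- function(v, factor) {
  if (factor == 1L) return(v)
  if (length(v) %% factor != 0L)
    stop_sflim(sprintf("length %d not divisible by rebin factor %d",
                       length(v), factor), "sflim_dimension_error")
  colSums(matrix(v, nrow = factor))
}
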