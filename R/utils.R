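# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a child RNG seed from a master seed
#'
#' Keeps every stage of the pipeline on its own reproducible stream while all
#' streams are functions of one user-supplied seed. Result stays below 2^31.
#'
#' @param seed master integer seed
#' @param offset integer stage offset (distinct per stage/layer/fold)
#' @return an integer seed
#' @export
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 1e6) * 2049 + as.numeric(offset) %% 2048)
}

#' Clamp predicted probabilities away from 0 and 1
#'
#' Vote fractions from an ensemble of `n_trees` trees are clamped to
#' \[1/(2 n_trees), 1 - 1/(2 n_trees)\] so that ratio operations (RSS) never
#' divide by zero.
#'
#' @param p numeric vector of probabilities
#' @param n_trees ensemble size
#' @return clamped numeric vector
#' @export
clamp_prob <- function(p, n_trees) {
  eps <- 1 / (2 * n_trees)
  pmin(pmax(p, eps), 1 - eps)
}

log_msg <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
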