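#' Upper-triangle pair index table
#'
#' Enumerates all unordered condition pairs (i < j) in the canonical
#' column-major upper-triangle order used throughout the package to store
#' RDMs as flat vectors.
#'
#' @param n Number of conditions.
#' @return A two-column integer matrix with columns `i` and `j`, one row per
#'   unordered pair, in the same order as `upper.tri()` of an `n x n` matrix.
#' @export
pair_index <- function(n) {
  stopifnot(n >= 2)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  m <- cbind(i = as.integer(idx[, "row"]), j = as.integer(idx[, "col"]))
  m[order(m[, "j"], m[, "i"]), , drop = FALSE]
}

#' Convert a flat pair vector to a symmetric square matrix
#'
#' @param v Numeric vector of length `n*(n-1)/2` in canonical pair order.
#' @param n Number of conditions.
#' @param diag Value to place on the diagonal (default 0).
#' @return An `n x n` symmetric matrix.
#' @export
squareform <- function(v, n, diag = 0) {
  stopifnot(length(v) == n * (n - 1) / 2)
  m <- matrix(diag, n, n)
  m[upper.tri(m)] <- v
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m
}

#' Extract the upper triangle of a square matrix as a flat pair vector
#'
#' @param m A square matrix.
#' @return Numeric vector in canonical pair order.
#' @export
unsquareform <- function(m) {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  m[upper.tri(m)]
}

#' Percentage accuracy of a monitoring task
#'
#' Summarizes behavioral hit counts as a rounded percentage, the convention
#' used when reporting in-scanner target-detection performance.
#'
#' @param n_correct Number of correct responses.
#' @param n_total Number of target trials.
#' @return Integer percentage, rounded half-up.
#' @export
accuracy_percent <- function(n_correct, n_total) {
  stopifnot(n_total >= 1, n_correct >= 0, n_correct <= n_total)
  as.integer(floor(100 * n_correct / n_total + 0.5))
}

# round half-up to `digits` decimals (base round() is banker's rounding)
round_half_up <- function(x, digits) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# derive a child RNG seed from a base seed; kept below 2^31
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(k) * 104729) %% 2147483647)
}
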