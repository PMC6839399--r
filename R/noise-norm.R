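#' Estimate voxel noise covariance from residual frames with shrinkage
#'
#' Per run, the population (1/N) sample covariance of the residual frames is
#' shrunk toward its diagonal, \eqn{\hat\Sigma = (1-\lambda) S + \lambda\,
#' \mathrm{diag}(S)}, and the shrunk covariances are averaged across runs.
#' The shrinkage weight is estimated analytically (Ledoit-Wolf/
#' Schafer-Strimmer style, target = diagonal) unless supplied.
#'
#' @param residuals List of `frames x V` matrices, one per run (or a single
#'   matrix, treated as one run).
#' @param lambda Shrinkage weight in \[0, 1\], or `NULL` for the analytic
#'   estimate (mean of the per-run estimates).
#' @return Object of class `noise_cov`: list with `sigma` (V x V), `lambda`,
#'   `n_runs`.
#' @export
estimate_noise_cov <- function(residuals, lambda = NULL) {
  if (is.matrix(residuals)) residuals <- list(residuals)
  if (!is.null(lambda) && (lambda < 0 || lambda > 1))
    stop("lambda must lie in [0, 1]")
  if (any(vapply(residuals, nrow, 1L) < 2))
    stop("need at least 2 residual frames per run")
  V <- ncol(residuals[[1]])
  S_bar <- matrix(0, V, V)
  lam_runs <- numeric(length(residuals))
  for (r in seq_along(residuals)) {
    X <- scale(residuals[[r]], center = TRUE, scale = FALSE)
    n <- nrow(X)
    S <- crossprod(X) / n                      # population convention
    S_bar <- S_bar + S
    if (is.null(lambda)) {
      # analytic shrinkage toward diag(S): lambda* = sum Var(s_ij) / sum s_ij^2
      # over off-diagonal cells, Var(s_ij) ~ n^2 (E[w^2] - s_ij^2)/(n-1)^3
      phi <- crossprod(X^2) / n
      var_s <- n^2 * (phi - S^2) / (n - 1)^3
      off <- upper.tri(S) | lower.tri(S)
      denom <- sum(S[off]^2)
      lam_runs[r] <- if (denom > 0) min(1, max(0, sum(var_s[off]) / denom)) else 1
    }
  }
  S_bar <- S_bar / length(residuals)
  lam <- if (is.null(lambda)) mean(lam_runs) else lambda
  sigma <- (1 - lam) * S_bar + lam * diag(diag(S_bar), V)
  ok <- !inherits(try(chol(sigma), silent = TRUE), "try-error")
  if (!ok) {
    if (lam == 0)
      stop("covariance is singular with lambda = 0; enable shrinkage ",
           "(lambda > 0 or lambda = NULL for the analytic estimate)")
    stop("shrunk covariance is not positive definite")
  }
  structure(list(sigma = sigma, lambda = lam, n_runs = length(residuals)),
            class = "noise_cov")
}

#' @export
print.noise_cov <- function(x, ...) {
  cat("<noise_cov> ", ncol(x$sigma), " voxels, lambda = ",
      signif(x$lambda, 3), ", ", x$n_runs, " runs\n", sep = "")
  invisible(x)
}

# inverse symmetric square root of a positive-definite matrix
inv_sqrtm <- function(sigma) {
  e <- eigen(sigma, symmetric = TRUE)
  if (any(e$values <= 0)) stop("covariance is not positive definite")
  e$vectors %*% (t(e$vectors) / sqrt(e$values))
}

#' Prewhiten beta patterns by the noise covariance
#'
#' Multiplies patterns by \eqn{\hat\Sigma^{-1/2}}, so that Euclidean
#' cross-validated distances on the whitened patterns equal Mahalanobis
#' cross-validated distances on the raw patterns.
#'
#' @param betas `conditions x V` matrix (or list of such matrices per run).
#' @param cov A `noise_cov` over the same V voxels.
#' @return Whitened matrix (or list of matrices).
#' @export
prewhiten <- function(betas, cov) {
  W <- inv_sqrtm(cov$sigma)
  if (is.list(betas)) lapply(betas, function(b) b %*% W) else betas %*% W
}

#' Cross-validated Mahalanobis (crossnobis) RDM
#'
#' For each condition pair (i, j),
#' \deqn{d_{ij} = \frac{1}{P\,R(R-1)} \sum_{m \ne n}
#'   (b_i^m - b_j^m)^\top \hat\Sigma^{-1} (b_i^n - b_j^n),}
#' over all ordered run pairs, where P is the voxel count. Cross-validation
#' across runs makes the estimator unbiased: its expectation is zero when
#' the true patterns are identical, so distances can be tested directly
#' against zero, and individual estimates may be negative.
#'
#' @param subject A `subject_data`.
#' @param voxels Integer vector of voxel (column) indices; `NULL` = all.
#' @param cov A `noise_cov` over those voxels; `NULL` estimates one from the
#'   subject's residuals restricted to `voxels`.
#' @return Object of class `rdm`: numeric vector over unordered condition
#'   pairs in canonical order, with attributes `n_conditions`, `subject`,
#'   `n_voxels`.
#' @export
crossnobis_rdm <- function(subject, voxels = NULL, cov = NULL) {
  R <- length(subject$betas)
  if (R < 2) stop("need at least 2 runs for cross-validation")
  if (is.null(voxels)) voxels <- seq_len(ncol(subject$betas[[1]]))
  if (is.null(cov))
    cov <- estimate_noise_cov(lapply(subject$resid, function(x)
      x[, voxels, drop = FALSE]))
  if (ncol(cov$sigma) != length(voxels))
    stop("covariance dimension does not match the voxel subset")
  B <- lapply(subject$betas, function(b) b[, voxels, drop = FALSE])
  Bw <- prewhiten(B, cov)
  n_cond <- nrow(Bw[[1]])
  P <- length(voxels)
  H <- matrix(0, n_cond, n_cond)
  for (m in seq_len(R - 1)) for (n in (m + 1):R) {
    G <- Bw[[m]] %*% t(Bw[[n]])
    H <- H + G + t(G)
  }
  dH <- diag(H)
  Dsq <- outer(dH, dH, "+") - H - t(H)
  d <- unsquareform(Dsq) / (P * R * (R - 1))
  new_rdm(d, n_cond, subject = subject$subject, n_voxels = P)
}

new_rdm <- function(values, n_conditions, ...) {
  structure(values, n_conditions = n_conditions, ..., class = "rdm")
}

#' @export
print.rdm <- function(x, ...) {
  cat("<rdm> ", attr(x, "n_conditions"), " conditions (",
      length(unclass(x)), " cells), range [",
      signif(min(x), 3), ", ", signif(max(x), 3), "]\n", sep = "")
  invisible(x)
}

#' Cellwise mean of a list of RDMs
#' @param rdms List of `rdm` vectors of equal length.
#' @return An `rdm` with the cellwise mean.
#' @export
mean_rdm <- function(rdms) {
  vals <- rowMeans(do.call(cbind, lapply(rdms, as.numeric)))
  new_rdm(vals, attr(rdms[[1]], "n_conditions"))
}

#' Write / read an RDM as CSV
#'
#' `write_rdm` writes both a long format (`condition_a, condition_b,
#' distance`) and, if `square = TRUE`, a square matrix with canonical
#' condition headers.
#'
#' @param rdm An `rdm`.
#' @param path Output CSV path (long format).
#' @param space Optional `condition_space` for condition labels.
#' @param square If `TRUE`, also write `<path>_square.csv`.
#' @return `path`, invisibly.
#' @export
write_rdm <- function(rdm, path, space = NULL, square = FALSE) {
  n <- attr(rdm, "n_conditions")
  pp <- pair_index(n)
  lab <- if (!is.null(space))
    with(space$conditions, paste(item, modality, model_id, sep = "_"))
  else as.character(seq_len(n))
  long <- data.frame(condition_a = lab[pp[, "i"]], condition_b = lab[pp[, "j"]],
                     distance = as.numeric(rdm))
  utils::write.csv(long, path, row.names = FALSE)
  if (square) {
    m <- squareform(as.numeric(rdm), n)
    dimnames(m) <- list(lab, lab)
    utils::write.csv(m, sub("\\.csv$", "_square.csv", path))
  }
  invisible(path)
}

#' @rdname write_rdm
#' @export
read_rdm <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  m <- length(long$distance)
  n <- (1 + sqrt(1 + 8 * m)) / 2
  if (n != round(n)) stop("cell count is not a triangular number")
  new_rdm(long$distance, as.integer(n))
}
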