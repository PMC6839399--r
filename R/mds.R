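#' Non-metric multidimensional scaling of a group-average RDM
#'
#' Kruskal's non-metric MDS (monotone-regression stress minimization),
#' consistent with the rank-based tau-a model fitting. Crossnobis RDMs may
#' contain negative cells; dissimilarities are shifted by their minimum to
#' be positive before embedding, which preserves ranks and is therefore
#' innocuous for a non-metric solution. The best of several random
#' restarts (plus a classical-scaling start) is returned.
#'
#' @param rdm An `rdm` (e.g., the cellwise group mean) over n conditions.
#' @param conditions Optional integer subset of conditions to embed
#'   (default: all).
#' @param dims Embedding dimensionality (default 2).
#' @param restarts Number of random restarts (default 10).
#' @param seed Integer seed; the result is deterministic given the seed.
#' @return Object of class `mds_embedding`: list with `points`
#'   (conditions x dims, mean-centered), `stress` (Kruskal stress-1 in
#'   \[0, 1\]), `restarts`, `seed`, `conditions`.
#' @export
nonmetric_mds <- function(rdm, conditions = NULL, dims = 2, restarts = 10,
                          seed = 1) {
  n <- attr(rdm, "n_conditions")
  D <- squareform(as.numeric(rdm), n)
  if (is.null(conditions)) conditions <- seq_len(n)
  if (length(conditions) < dims + 1)
    stop("need more conditions than embedding dimensions")
  D <- D[conditions, conditions]
  off <- upper.tri(D) | lower.tri(D)
  if (min(D[off]) <= 0) {                   # rank-preserving positive shift
    eps <- 1e-6 * max(abs(D[off]) + 1e-12)
    D[off] <- D[off] - min(D[off]) + eps
  }
  set.seed(seed)
  dd <- stats::as.dist(D)
  best <- NULL
  for (k in seq_len(restarts)) {
    init <- if (k == 1) {
      stats::cmdscale(dd, k = dims)
    } else {
      matrix(stats::rnorm(length(conditions) * dims), ncol = dims)
    }
    if (ncol(init) < dims)                  # degenerate classical start
      init <- cbind(init, matrix(0, nrow(init), dims - ncol(init)))
    fit <- try(suppressWarnings(
      MASS::isoMDS(dd, y = init, k = dims, trace = FALSE)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  if (is.null(best)) stop("MDS failed for every restart")
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  structure(list(points = pts, stress = best$stress / 100,
                 restarts = restarts, seed = seed, conditions = conditions),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat("<mds_embedding> ", nrow(x$points), " conditions in ",
      ncol(x$points), "D, stress-1 = ", signif(x$stress, 3), "\n", sep = "")
  invisible(x)
}

#' Category-by-modality centroids of an MDS embedding
#'
#' Mean embedding coordinate of the conditions in each (category, modality)
#' cell -- e.g., the 3 items x 2 speakers/signers of one category in one
#' modality.
#'
#' @param embedding An `mds_embedding`.
#' @param space A `condition_space`.
#' @return Data frame with `category`, `modality`, one column per
#'   embedding dimension, and `n_conditions`.
#' @export
category_centroids <- function(embedding, space) {
  cond <- space$conditions[embedding$conditions, , drop = FALSE]
  if (nrow(cond) != nrow(embedding$points))
    stop("embedding does not cover the given conditions")
  key <- interaction(cond$category, cond$modality, drop = TRUE)
  cent <- apply(embedding$points, 2, function(col) tapply(col, key, mean))
  if (is.null(dim(cent))) cent <- matrix(cent, nrow = 1)
  parts <- do.call(rbind, strsplit(levels(key), ".", fixed = TRUE))
  out <- data.frame(category = parts[, 1], modality = parts[, 2],
                    stringsAsFactors = FALSE)
  colnames(cent) <- paste0("dim", seq_len(ncol(cent)))
  out <- cbind(out, as.data.frame(cent))
  out$n_conditions <- as.integer(table(key)[levels(key)])
  rownames(out) <- NULL
  out
}

#' Write MDS coordinates as CSV
#'
#' @param embedding An `mds_embedding`.
#' @param space A `condition_space` for condition labels.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, space, path) {
  cond <- space$conditions[embedding$conditions, , drop = FALSE]
  out <- cbind(cond[, c("item", "category", "modality", "model_id")],
               as.data.frame(embedding$points))
  names(out)[-(1:4)] <- paste0("dim", seq_len(ncol(embedding$points)))
  out$stress <- embedding$stress
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
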