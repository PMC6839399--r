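#' Spherical searchlight offsets on an anisotropic voxel grid
#'
#' All integer voxel displacements whose physical center-to-center distance
#' is at most `radius` mm. On a 3 x 3 x 4 mm grid an 8 mm sphere contains
#' 65 voxels.
#'
#' @param voxel_size Numeric 3-vector of voxel dimensions, mm.
#' @param radius Sphere radius, mm.
#' @return Object of class `searchlight_spec`: list with `radius`,
#'   `voxel_size`, and `offsets` (k x 3 integer matrix, symmetric under
#'   negation, including the origin).
#' @export
sphere_offsets <- function(voxel_size, radius) {
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  if (radius < 0) stop("radius must be non-negative")
  mx <- floor(radius / voxel_size)
  g <- as.matrix(expand.grid(-mx[1]:mx[1], -mx[2]:mx[2], -mx[3]:mx[3]))
  keep <- sqrt((g[, 1] * voxel_size[1])^2 + (g[, 2] * voxel_size[2])^2 +
                 (g[, 3] * voxel_size[3])^2) <= radius
  off <- g[keep, , drop = FALSE]
  dimnames(off) <- NULL
  structure(list(radius = radius, voxel_size = voxel_size,
                 offsets = matrix(as.integer(off), ncol = 3)),
            class = "searchlight_spec")
}

#' @export
print.searchlight_spec <- function(x, ...) {
  cat("<searchlight_spec> radius ", x$radius, " mm on ",
      paste(x$voxel_size, collapse = "x"), " mm voxels: ",
      nrow(x$offsets), " voxels per sphere\n", sep = "")
  invisible(x)
}

new_stat_map <- function(values, dims, statistic, ...) {
  structure(list(values = array(values, dims), dims = dims,
                 statistic = statistic, ...),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  v <- x$values[!is.na(x$values)]
  cat("<stat_map> ", x$statistic, " on ", paste(x$dims, collapse = "x"),
      " grid; ", length(v), " in-mask voxels, range [",
      signif(min(v), 3), ", ", signif(max(v), 3), "]\n", sep = "")
  invisible(x)
}

#' Map mean masked crossnobis distances with a spherical searchlight
#'
#' At each in-mask voxel, a crossnobis RDM is computed over the sphere's
#' voxels (with per-sphere shrinkage noise covariance estimated from the
#' subject's residual frames) and the mean of the selected cells is
#' returned to the center voxel. Spheres truncated at mask edges are kept
#' if at least `min_frac` of the offsets fall in-mask; the per-voxel
#' normalization of the crossnobis distance keeps truncated spheres
#' comparable.
#'
#' @param subject A `subject_data`.
#' @param spec A `searchlight_spec`.
#' @param statistic A `cell_mask` naming the cells to average (e.g.
#'   `within_modality_combined`, `within_speech_across_speaker`).
#' @param mask Logical vector/array over the grid (`NULL` = whole grid).
#' @param lambda Shrinkage weight, or `NULL` for the analytic estimate.
#' @param min_frac Minimum in-mask fraction of sphere offsets (default 0.5).
#' @param return_rdms If `TRUE`, also return the per-center RDM store used
#'   later for ROI-level RDM averaging.
#' @return A `stat_map`; when `return_rdms = TRUE` it carries `rdm_store`,
#'   a list with `rdms` (centers x cells matrix) and `centers` (linear
#'   voxel indices).
#' @export
run_searchlight <- function(subject, spec, statistic, mask = NULL,
                            lambda = NULL, min_frac = 0.5,
                            return_rdms = FALSE) {
  dims <- subject$dims
  V <- prod(dims)
  if (is.null(mask)) mask <- rep(TRUE, V)
  mask <- as.logical(mask)
  if (length(mask) != V) stop("mask length does not match the grid")
  if (!any(mask)) stop("no in-mask centers")
  res <- searchlight_crossnobis(subject$betas, subject$resid,
                                as.integer(dims), mask, spec$offsets,
                                min_frac,
                                if (is.null(lambda)) -1 else lambda,
                                statistic$select, return_rdms)
  out <- new_stat_map(res$map, dims, statistic$name,
                      subject = subject$subject)
  if (return_rdms)
    out$rdm_store <- list(rdms = res$rdms, centers = res$centers,
                          n_conditions = statistic$n_conditions)
  out
}

# stack subject maps into an n x V matrix
maps_to_matrix <- function(maps) {
  vals <- lapply(maps, function(m) {
    if (inherits(m, "stat_map")) as.numeric(m$values) else as.numeric(m)
  })
  V <- length(vals[[1]])
  if (any(vapply(vals, length, 1L) != V)) stop("subject maps differ in grid")
  do.call(rbind, vals)
}

# voxelwise one-sample t statistics for an n x V matrix; zero-variance
# voxels yield NaN
t_stat_rows <- function(X) {
  n <- nrow(X)
  m <- colMeans(X)
  v <- (colSums(X^2) - n * m^2) / (n - 1)
  t <- m / sqrt(v / n)
  t[v <= 0] <- NaN
  t
}

#' Voxelwise group t map across subject searchlight maps
#'
#' @param maps List of subject `stat_map`s (or 3D arrays) on one grid.
#' @param test `"one_sample"` (greater-than-zero) or `"paired"`
#'   (differences `maps - maps2`).
#' @param maps2 Second map set for the paired test.
#' @return A `stat_map` of t values with a `df` field; voxels with zero
#'   variance (or missing in any subject) are `NaN`/`NA`.
#' @export
group_map <- function(maps, test = c("one_sample", "paired"), maps2 = NULL) {
  test <- match.arg(test)
  if (length(maps) < 2) stop("need at least 2 subjects")
  X <- maps_to_matrix(maps)
  if (test == "paired") {
    if (is.null(maps2)) stop("paired test needs maps2")
    X <- X - maps_to_matrix(maps2)
  }
  dims <- if (inherits(maps[[1]], "stat_map")) maps[[1]]$dims else dim(maps[[1]])
  t <- t_stat_rows(X)
  new_stat_map(t, dims, paste0("group_t_", test), df = nrow(X) - 1)
}

# connected components of a logical 3D array under 18-connectivity
# (faces + edges); returns a list of linear-index vectors, one per
# component, largest first
label_components <- function(mask_arr) {
  dims <- dim(mask_arr)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) %in% c(1, 2), , drop = FALSE]
  idx <- which(mask_arr)
  if (!length(idx)) return(list())
  seen <- array(FALSE, dims)
  comps <- list()
  for (start in idx) {
    if (seen[start]) next
    queue <- start
    seen[start] <- TRUE
    comp <- integer()
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      comp <- c(comp, v)
      z <- (v - 1) %/% (dims[1] * dims[2])
      rem <- (v - 1) %% (dims[1] * dims[2])
      y <- rem %/% dims[1]; x <- rem %% dims[1]
      xx <- x + nb[, 1]; yy <- y + nb[, 2]; zz <- z + nb[, 3]
      ok <- xx >= 0 & xx < dims[1] & yy >= 0 & yy < dims[2] &
        zz >= 0 & zz < dims[3]
      lin <- xx[ok] + yy[ok] * dims[1] + zz[ok] * dims[1] * dims[2] + 1
      lin <- lin[mask_arr[lin] & !seen[lin]]
      seen[lin] <- TRUE
      queue <- c(queue, lin)
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps[order(-lengths(comps))]
}

#' Cluster-level inference by sign-flip permutation with FDR correction
#'
#' The group t map is thresholded one-sided at the t quantile for
#' `cluster_forming_p`; connected components (18-connectivity) form
#' clusters; cluster-level p values come from a sign-flip permutation null
#' of the maximum cluster extent; Benjamini-Hochberg correction across
#' clusters at `q` marks survivors. Under subject exchangeability the
#' sign-flip null is exact.
#'
#' @param maps List of subject `stat_map`s (one-sample test) or first
#'   member of a pair.
#' @param test,maps2 As in [group_map()].
#' @param cluster_forming_p Uncorrected voxelwise threshold (default 0.005).
#' @param q FDR level across clusters (default 0.05).
#' @param n_permutations Number of sign-flip permutations (default 1000).
#' @param seed Seed for the permutation draws.
#' @return Object of class `cluster_table`: data frame with one row per
#'   cluster (`id`, `peak_x/y/z`, `peak_t`, `extent`, `p`, `q_value`,
#'   `survives`), with the cluster voxel lists in attribute `"voxels"` and
#'   the group `stat_map` in attribute `"t_map"`. Empty (0-row) when no
#'   voxel is suprathreshold.
#' @export
cluster_inference <- function(maps, test = c("one_sample", "paired"),
                              maps2 = NULL, cluster_forming_p = 0.005,
                              q = 0.05, n_permutations = 1000, seed = 1) {
  test <- match.arg(test)
  X <- maps_to_matrix(maps)
  if (test == "paired") {
    if (is.null(maps2)) stop("paired test needs maps2")
    X <- X - maps_to_matrix(maps2)
  }
  dims <- if (inherits(maps[[1]], "stat_map")) maps[[1]]$dims else dim(maps[[1]])
  n <- nrow(X)
  df <- n - 1
  thr <- stats::qt(1 - cluster_forming_p, df)
  tobs <- t_stat_rows(X)
  tmap <- new_stat_map(tobs, dims, "group_t", df = df)
  supra <- array(!is.na(tobs) & !is.nan(tobs) & tobs > thr, dims)
  comps <- label_components(supra)
  empty <- data.frame(id = integer(), peak_x = integer(), peak_y = integer(),
                      peak_z = integer(), peak_t = numeric(),
                      extent = integer(), p = numeric(), q_value = numeric(),
                      survives = logical())
  if (!length(comps)) {
    attr(empty, "voxels") <- list(); attr(empty, "t_map") <- tmap
    class(empty) <- c("cluster_table", "data.frame")
    return(empty)
  }
  set.seed(seed)
  null_max <- numeric(n_permutations)
  for (b in seq_len(n_permutations)) {
    s <- sample(c(-1, 1), n, replace = TRUE)
    tp <- t_stat_rows(X * s)
    sp <- array(!is.na(tp) & !is.nan(tp) & tp > thr, dims)
    cc <- label_components(sp)
    null_max[b] <- if (length(cc)) length(cc[[1]]) else 0
  }
  rows <- lapply(seq_along(comps), function(k) {
    vx <- comps[[k]]
    peak <- vx[which.max(tobs[vx])]
    co <- arrayInd(peak, dims)
    data.frame(id = k, peak_x = co[1], peak_y = co[2], peak_z = co[3],
               peak_t = max(tobs[vx]), extent = length(vx),
               p = (1 + sum(null_max >= length(vx))) / (1 + n_permutations))
  })
  tab <- do.call(rbind, rows)
  tab$q_value <- stats::p.adjust(tab$p, method = "BH")
  tab$survives <- tab$q_value < q
  attr(tab, "voxels") <- comps
  attr(tab, "t_map") <- tmap
  class(tab) <- c("cluster_table", "data.frame")
  tab
}
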