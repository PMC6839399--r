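#' Turn surviving clusters into regions of interest
#'
#' @param cluster_table A `cluster_table` from [cluster_inference()].
#' @param prefix Label prefix for ROI ids.
#' @param selector Optional `cell_mask` recording which cell statistic
#'   defined the clusters (stored as provenance for the orthogonality
#'   guard).
#' @return Object of class `roi_set`: list of ROIs, each a list with `id`,
#'   `voxels`, `provenance` (list with `selector`, `loo = FALSE`).
#'   Empty, with a warning, when no cluster survives.
#' @export
clusters_to_rois <- function(cluster_table, prefix = "roi", selector = NULL) {
  keep <- which(cluster_table$survives)
  if (!length(keep)) {
    warning("no surviving clusters; returning an empty ROI set")
    return(structure(list(), class = "roi_set"))
  }
  voxels <- attr(cluster_table, "voxels")
  rois <- lapply(seq_along(keep), function(k) {
    list(id = paste0(prefix, "_", k), voxels = voxels[[keep[k]]],
         provenance = list(selector = selector, loo = FALSE))
  })
  structure(rois, class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  if (!is.null(attr(x, "families"))) {
    cat("<roi_set> ", length(attr(x, "families")),
        " leave-one-out families\n", sep = "")
  } else {
    cat("<roi_set> ", length(x), " ROIs (",
        paste(vapply(x, function(r) length(r$voxels), 1L), collapse = ", "),
        " voxels)\n", sep = "")
  }
  invisible(x)
}

#' Average per-searchlight RDMs over an ROI
#'
#' Averages, cell by cell, the RDMs of every searchlight whose center lies
#' inside the ROI, yielding one representative RDM per region (per
#' subject).
#'
#' @param rdm_store The `rdm_store` from [run_searchlight()] (fields
#'   `rdms`, `centers`, `n_conditions`).
#' @param roi An ROI (list with `voxels`) or a plain integer vector of
#'   voxel indices.
#' @return An `rdm`.
#' @export
roi_mean_rdm <- function(rdm_store, roi) {
  voxels <- if (is.list(roi)) roi$voxels else roi
  rows <- which(rdm_store$centers %in% voxels)
  if (!length(rows)) stop("ROI contains no stored searchlight centers")
  vals <- colMeans(rdm_store$rdms[rows, , drop = FALSE])
  new_rdm(vals, rdm_store$n_conditions, n_centers = length(rows))
}

#' Leave-one-participant-out ROIs
#'
#' For each subject s, the group map is re-estimated from all other
#' subjects, thresholded voxelwise at `threshold_p` (uncorrected,
#' one-sided), and its connected components form subject s's ROI family.
#' Because family s was defined without subject s's data, fitting
#' non-selection-orthogonal models (the speaker/signer identity models) in
#' it is unbiased.
#'
#' @param maps List of subject `stat_map`s (or 3D arrays).
#' @param test,maps2 As in [group_map()].
#' @param threshold_p Uncorrected voxelwise threshold (default 0.001).
#' @param selector Optional `cell_mask` recorded as provenance.
#' @return Object of class `roi_set` with attribute `"families"`: a list of
#'   length `n`, each a list of ROIs as in [clusters_to_rois()] but with
#'   `provenance$loo = TRUE` and `provenance$excluded_subject`. Families
#'   with no suprathreshold voxels are empty, with a warning.
#' @export
leave_one_out_rois <- function(maps, test = c("one_sample", "paired"),
                               maps2 = NULL, threshold_p = 0.001,
                               selector = NULL) {
  test <- match.arg(test)
  if (length(maps) < 2) stop("need at least 2 subjects")
  X <- maps_to_matrix(maps)
  if (test == "paired") {
    if (is.null(maps2)) stop("paired test needs maps2")
    X <- X - maps_to_matrix(maps2)
  }
  dims <- if (inherits(maps[[1]], "stat_map")) maps[[1]]$dims else dim(maps[[1]])
  n <- nrow(X)
  families <- vector("list", n)
  for (s in seq_len(n)) {
    Xs <- X[-s, , drop = FALSE]
    if (nrow(Xs) < 2) {
      warning("family ", s, ": fewer than 2 defining subjects (df = 0); ",
              "empty family")
      families[[s]] <- list()
      next
    }
    df <- nrow(Xs) - 1
    t <- t_stat_rows(Xs)
    thr <- stats::qt(1 - threshold_p, df)
    supra <- array(!is.na(t) & !is.nan(t) & t > thr, dims)
    comps <- label_components(supra)
    if (!length(comps))
      warning("family ", s, ": no suprathreshold voxels at p < ",
              threshold_p)
    families[[s]] <- lapply(seq_along(comps), function(k)
      list(id = paste0("loo", s, "_", k), voxels = comps[[k]],
           provenance = list(selector = selector, loo = TRUE,
                             excluded_subject = s)))
  }
  structure(list(), families = families, class = "roi_set")
}

#' Number of leave-one-out ROI families in a set
#'
#' @param roi_set An `roi_set` from [leave_one_out_rois()].
#' @param nonempty If `TRUE` (default), count only families that contain at
#'   least one cluster.
#' @return Integer count.
#' @export
n_families <- function(roi_set, nonempty = TRUE) {
  fam <- attr(roi_set, "families")
  if (is.null(fam)) stop("not a leave-one-out ROI set")
  if (nonempty) sum(lengths(fam) > 0) else length(fam)
}

#' Orthogonality guard for model fitting inside a selected ROI
#'
#' The selection statistic is a mean over cells; because correlation
#' removes the mean, any model whose tested cells lie inside the selecting
#' cells is orthogonal to selection. A model that predicts a mean
#' difference between the selecting cells and other tested cells (the
#' speaker/signer identity models) is not: fitting it in a same-data ROI
#' is circular and is blocked unless the ROI is a leave-one-out family.
#'
#' @param model A `model_rdm`.
#' @param provenance ROI provenance: list with `selector` (a `cell_mask`)
#'   and `loo` (logical).
#' @return `"pass"` or `"violation"`.
#' @export
orthogonality_guard <- function(model, provenance) {
  if (is.null(provenance) || is.null(provenance$loo))
    stop("unknown ROI provenance")
  if (isTRUE(provenance$loo)) return("pass")
  if (is.null(provenance$selector) ||
      !inherits(provenance$selector, "cell_mask"))
    stop("unknown ROI provenance: no selector cell mask recorded")
  tested <- model$mask$select
  selecting <- provenance$selector$select
  inside <- tested & selecting
  outside <- tested & !selecting
  if (!any(outside)) return("pass")
  mu_in <- mean(model$values[inside])
  mu_out <- mean(model$values[outside])
  if (is.na(mu_in) || is.na(mu_out)) return("pass")
  if (abs(mu_in - mu_out) > 1e-12) "violation" else "pass"
}
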