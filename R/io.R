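#' Write a synthetic subject to NIfTI volumes plus tables
#'
#' One 4D NIfTI per run per kind (`beta_run-<r>.nii`: conditions along the
#' 4th axis; `resid_run-<r>.nii`: residual frames along the 4th axis), a
#' condition table CSV, and a JSON sidecar recording grid geometry and the
#' generator seed.
#'
#' @param subject A `subject_data`.
#' @param space A `condition_space`.
#' @param dir Output directory (created if needed).
#' @return The sidecar path, invisibly.
#' @export
write_subject_data <- function(subject, space, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dims <- subject$dims
  for (r in seq_along(subject$betas)) {
    beta_arr <- array(t(subject$betas[[r]]), c(dims, nrow(subject$betas[[r]])))
    resid_arr <- array(t(subject$resid[[r]]), c(dims, nrow(subject$resid[[r]])))
    RNifti::writeNifti(
      RNifti::asNifti(beta_arr, pixdim = c(subject$voxel_size, 1)),
      file.path(dir, sprintf("beta_run-%d.nii", r)))
    RNifti::writeNifti(
      RNifti::asNifti(resid_arr, pixdim = c(subject$voxel_size, 1)),
      file.path(dir, sprintf("resid_run-%d.nii", r)))
  }
  write_condition_table(space, file.path(dir, "conditions.csv"))
  sidecar <- file.path(dir, "subject.json")
  jsonlite::write_json(
    list(subject = subject$subject, seed = subject$seed,
         dims = dims, voxel_size = subject$voxel_size,
         n_runs = length(subject$betas)),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Read per-run beta and residual volumes into a `subject_data`
#'
#' Volumes must share one grid; the condition table must cover every
#' condition of the canonical space, and betas are reordered to canonical
#' condition order using its `canonical_index` column, so a shuffled table
#' yields identical downstream RDMs.
#'
#' @param beta_paths,resid_paths Character vectors of 4D NIfTI paths, one
#'   per run, in run order.
#' @param condition_csv Path to the condition table (row order = volume
#'   order along the 4th axis of each beta file).
#' @param mask_path Optional NIfTI mask (stored as attribute `"mask"`).
#' @param subject Subject id for bookkeeping.
#' @return A `subject_data`.
#' @export
read_subject_data <- function(beta_paths, resid_paths, condition_csv,
                              mask_path = NULL, subject = NA) {
  if (length(beta_paths) != length(resid_paths))
    stop("beta and residual run counts differ")
  tab <- utils::read.csv(condition_csv, stringsAsFactors = FALSE)
  need <- c("item", "modality", "model_id", "canonical_index")
  if (!all(need %in% names(tab)))
    stop("condition table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  n_cond <- nrow(tab)
  if (anyDuplicated(tab$canonical_index) ||
      !setequal(tab$canonical_index, seq_len(n_cond))) {
    missing <- setdiff(seq_len(n_cond), tab$canonical_index)
    stop("condition table does not cover the canonical space",
         if (length(missing)) paste0("; missing canonical index ",
                                     paste(missing, collapse = ", ")))
  }
  ord <- order(tab$canonical_index)
  dims <- NULL
  betas <- vector("list", length(beta_paths))
  resid <- vector("list", length(resid_paths))
  voxel_size <- NULL
  for (r in seq_along(beta_paths)) {
    b <- RNifti::readNifti(beta_paths[r])
    e <- RNifti::readNifti(resid_paths[r])
    if (is.null(dims)) {
      dims <- dim(b)[1:3]
      voxel_size <- RNifti::pixdim(b)[1:3]
    }
    if (!all(dim(b)[1:3] == dims) || !all(dim(e)[1:3] == dims))
      stop("grid mismatch across runs/kinds")
    if (dim(b)[4] != n_cond)
      stop("run ", r, ": ", dim(b)[4], " beta volumes for ", n_cond,
           " conditions")
    bm <- t(matrix(b, prod(dims)))
    betas[[r]] <- bm[ord, , drop = FALSE]
    resid[[r]] <- t(matrix(e, prod(dims)))
  }
  out <- structure(list(betas = betas, resid = resid, dims = dims,
                        voxel_size = voxel_size, subject = subject,
                        seed = NA),
                   class = "subject_data")
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    if (!all(dim(m)[1:3] == dims)) stop("mask grid mismatch")
    attr(out, "mask") <- as.logical(m > 0)
  }
  out
}

#' Write a stat map (or voxel mask) as NIfTI-1
#'
#' @param map A `stat_map`, or a numeric/logical 3D array.
#' @param path Output path.
#' @param voxel_size Voxel size in mm (3-vector).
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path, voxel_size = c(3, 3, 4)) {
  arr <- if (inherits(map, "stat_map")) map$values else map
  RNifti::writeNifti(RNifti::asNifti(arr * 1, pixdim = voxel_size), path)
  invisible(path)
}

#' Read a stat map from NIfTI
#' @param path NIfTI path.
#' @param statistic Statistic name to record.
#' @return A `stat_map`.
#' @export
read_stat_map <- function(path, statistic = "unknown") {
  img <- RNifti::readNifti(path)
  new_stat_map(as.numeric(img), dim(img)[1:3], statistic)
}

#' Write / read a scene configuration as YAML
#'
#' Region voxel indices are stored explicitly so a config round-trips
#' exactly.
#'
#' @param config A `scene_config`.
#' @param path YAML path.
#' @return `write_scene_config`: `path`, invisibly; `read_scene_config`:
#'   a `scene_config`.
#' @export
write_scene_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(scene_config, raw[c("n_subjects", "n_runs", "grid_dims",
                              "voxel_size", "noise_sd", "smooth_fwhm",
                              "n_residual_frames", "subject_jitter_sd",
                              "base_amplitude", "regions", "seed")])
}

#' Write a cluster table as CSV
#' @param tab A `cluster_table`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(tab, path) {
  utils::write.csv(as.data.frame(tab), path, row.names = FALSE)
  invisible(path)
}
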