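#' Searchlight discovery followed by ROI model fitting
#'
#' The package's end-to-end analysis: (1) a per-subject searchlight maps
#' the mean of the selected crossnobis cells over the grid, persisting
#' per-center RDMs; (2) group cluster inference (sign-flip permutation,
#' FDR across clusters) defines ROIs; (3) per ROI and subject, searchlight
#' RDMs are averaged into one representative RDM and the model battery is
#' fit with tau-a; (4) speaker/signer identity models, which are not
#' orthogonal to ROI selection, are fit in leave-one-participant-out ROIs
#' matched to each full-group ROI by maximal spatial overlap.
#'
#' @param cohort A `cohort` from [generate_cohort()] (or a compatible list
#'   with `subjects`, `space`, `config`).
#' @param features Item x feature matrix for the semantic model (default:
#'   synthetic norms generated from the cohort seed).
#' @param spec A `searchlight_spec` (default 8 mm radius on the cohort's
#'   voxel size).
#' @param statistic Selector name for the discovery statistic (default
#'   `"within_modality_combined"`).
#' @param cluster_forming_p,q,n_permutations,seed Cluster inference
#'   parameters, see [cluster_inference()].
#' @param loo_threshold_p Threshold for [leave_one_out_rois()].
#' @param lambda Shrinkage weight (`NULL` = analytic).
#' @param fit_identity Fit identity models in leave-one-out ROIs.
#' @param min_frac Minimum in-mask sphere fraction.
#' @return Object of class `rsa_pipeline`: list with `maps`, `clusters`,
#'   `rois`, `fits` (one `region_fit` per ROI), `loo` (the leave-one-out
#'   `roi_set`), `seed`.
#' @export
run_roi_pipeline <- function(cohort, features = NULL,
                             spec = sphere_offsets(cohort$config$voxel_size, 8),
                             statistic = "within_modality_combined",
                             cluster_forming_p = 0.005, q = 0.05,
                             n_permutations = 500, seed = 1,
                             loo_threshold_p = 0.001, lambda = NULL,
                             fit_identity = TRUE, min_frac = 0.5) {
  space <- cohort$space
  if (is.null(features))
    features <- if (!is.null(cohort$features)) cohort$features
      else generate_feature_norms(space, seed = child_seed(seed, 77))
  stat_mask <- cell_mask(space, statistic)
  maps <- list(); stores <- list()
  for (s in seq_along(cohort$subjects)) {
    sm <- run_searchlight(cohort$subjects[[s]], spec, stat_mask,
                          lambda = lambda, min_frac = min_frac,
                          return_rdms = TRUE)
    stores[[s]] <- sm$rdm_store
    sm$rdm_store <- NULL
    maps[[s]] <- sm
  }
  clusters <- cluster_inference(maps, "one_sample",
                                cluster_forming_p = cluster_forming_p,
                                q = q, n_permutations = n_permutations,
                                seed = seed)
  rois <- suppressWarnings(clusters_to_rois(clusters, selector = stat_mask))
  loo <- if (fit_identity && length(rois))
    suppressWarnings(leave_one_out_rois(maps, threshold_p = loo_threshold_p,
                                        selector = stat_mask))
  else NULL
  fits <- lapply(rois, function(roi) {
    rdms <- lapply(stores, roi_mean_rdm, roi = roi)
    fit <- fit_models_in_region(rdms, space, features,
                                provenance = roi$provenance,
                                alpha_k = max(1, length(rois)))
    if (!is.null(loo))
      fit <- add_identity_loo_fits(fit, roi, loo, stores, space, rdms)
    fit
  })
  names(fits) <- vapply(rois, `[[`, "", "id")
  structure(list(maps = maps, clusters = clusters, rois = rois, fits = fits,
                 loo = loo, seed = seed, statistic = statistic),
            class = "rsa_pipeline")
}

# fit the speaker/signer identity models using the leave-one-out family
# matched to `roi` by maximal voxel overlap, then refresh the verdict
add_identity_loo_fits <- function(fit, roi, loo, stores, space, full_rdms) {
  families <- attr(loo, "families")
  n <- length(stores)
  loo_rdms <- vector("list", n)
  for (s in seq_len(n)) {
    fam <- families[[s]]
    if (!length(fam)) next
    overlap <- vapply(fam, function(cl)
      length(intersect(cl$voxels, roi$voxels)), 1L)
    if (max(overlap) == 0) next
    loo_rdms[[s]] <- roi_mean_rdm(stores[[s]], fam[[which.max(overlap)]])
  }
  keep <- which(!vapply(loo_rdms, is.null, TRUE))
  if (length(keep) < 3) {
    fit$notes <- c(fit$notes,
                   "identity models not fit: fewer than 3 usable leave-one-out ROIs")
    return(fit)
  }
  for (mo in space$modalities) {
    mod <- identity_model(space, mo)
    tau <- vapply(loo_rdms[keep], function(r) tau_a(r, mod), 0)
    z <- tau_to_z(tau)$z
    gt <- one_sample_t(z)
    nc <- noise_ceiling(loo_rdms[keep], mod$mask)
    fit$group <- rbind(fit$group, data.frame(
      model = paste0("identity_", mo), mask = mod$mask$name,
      n_cells = mask_size(mod$mask), t = gt$t, df = gt$df, p = gt$p,
      d_z = gt$d_z, ceiling_lower = nc$lower, ceiling_upper = nc$upper,
      significant = gt$p < fit$alpha, stringsAsFactors = FALSE))
    fit$fits <- rbind(fit$fits, data.frame(
      subject = keep, model = paste0("identity_", mo),
      mask = mod$mask$name, n_cells = mask_size(mod$mask), tau = tau,
      r = tau_to_z(tau)$r, z = z, stringsAsFactors = FALSE))
  }
  fit$notes <- setdiff(fit$notes, grep("^identity_", fit$notes, value = TRUE))
  fit$verdict <- region_verdict(fit$group, fit$alpha)
  fit
}

#' @export
print.rsa_pipeline <- function(x, ...) {
  cat("<rsa_pipeline> statistic ", x$statistic, ": ",
      sum(x$clusters$survives), " surviving cluster(s)\n", sep = "")
  for (nm in names(x$fits))
    cat("  ", nm, ": verdict ", x$fits[[nm]]$verdict, "\n", sep = "")
  invisible(x)
}

#' Write a markdown report for a pipeline result
#'
#' Summarizes clusters, per-ROI model fits with noise ceilings, verdicts,
#' and provenance (seed, package version).
#'
#' @param pipeline An `rsa_pipeline`.
#' @param path Output markdown path.
#' @return `path`, invisibly.
#' @export
write_report <- function(pipeline, path) {
  md <- c(
    "# RSA pipeline report", "",
    paste0("- package: crossnobis ",
           as.character(utils::packageVersion("crossnobis"))),
    paste0("- seed: ", pipeline$seed),
    paste0("- discovery statistic: ", pipeline$statistic), "",
    "## Clusters", "")
  tab <- as.data.frame(pipeline$clusters)
  md <- c(md, if (nrow(tab)) df_to_md(tab) else "(no suprathreshold clusters)",
          "")
  for (nm in names(pipeline$fits)) {
    fit <- pipeline$fits[[nm]]
    md <- c(md, paste0("## ", nm, " - verdict: ", fit$verdict), "",
            paste0("adjusted alpha = ", fit$alpha), "",
            df_to_md(fit$group), "", "### Model comparisons", "",
            df_to_md(fit$paired), "")
    if (length(fit$notes)) md <- c(md, paste0("> ", fit$notes), "")
  }
  writeLines(md, path)
  invisible(path)
}

df_to_md <- function(df) {
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 4))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}

#' Write a full synthetic scene to disk
#'
#' Materializes a cohort the way a scanner-side pipeline would hand it
#' over: per-subject beta and residual NIfTI volumes, the condition and
#' design tables, synthetic feature norms, the scene config as YAML, and
#' a JSON provenance sidecar with the seed.
#'
#' @param config A `scene_config`.
#' @param dir Output directory.
#' @param seed Integer seed.
#' @return The directory, invisibly.
#' @export
simulate_scene_to_disk <- function(config, dir, seed = config$seed) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cohort <- generate_cohort(config, seed = seed)
  for (s in seq_along(cohort$subjects))
    write_subject_data(cohort$subjects[[s]], cohort$space,
                       file.path(dir, sprintf("sub-%02d", s)))
  design <- generate_design(config, cohort$space, seed = child_seed(seed, 1))
  utils::write.csv(design, file.path(dir, "design.csv"), row.names = FALSE)
  norms <- generate_feature_norms(cohort$space, seed = child_seed(seed, 77))
  utils::write.csv(norms, file.path(dir, "feature_norms.csv"))
  write_scene_config(config, file.path(dir, "scene.yaml"))
  jsonlite::write_json(list(seed = seed, n_subjects = config$n_subjects),
                       file.path(dir, "provenance.json"), auto_unbox = TRUE)
  invisible(dir)
}
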