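#' Kendall tau-a rank correlation
#'
#' \eqn{\tau_a = (C - D) / [m(m-1)/2]} over all cell pairs, with ties in
#' either variable counting as neither concordant nor discordant. Tau-a is
#' used in preference to Pearson, Spearman or tau-b because model RDMs
#' contain many tied predictions, and tau-a does not reward a model for
#' predicting ties. Two implementations are provided: an O(m^2) brute-force
#' reference and an O(m log m) merge-sort fast path; they agree exactly.
#'
#' @param data An `rdm` (or numeric vector).
#' @param model A `model_rdm` (or numeric vector of the same length as
#'   `data`). When both are package objects, values are compared over the
#'   model's tested-cell mask.
#' @param method `"fast"` (merge-sort) or `"brute"` (all-pairs reference).
#' @return Tau-a in \[-1, 1\].
#' @export
tau_a <- function(data, model, method = c("fast", "brute")) {
  method <- match.arg(method)
  if (inherits(model, "model_rdm")) {
    sel <- model$mask$select
    y <- model$values[sel]
    x <- as.numeric(data)[sel]
  } else {
    x <- as.numeric(data)
    y <- as.numeric(model)
  }
  if (length(x) != length(y)) stop("data and model lengths differ")
  m <- length(x)
  if (m < 3) stop("need at least 3 cells")
  if (length(unique(y)) < 2)
    stop("model is constant over the mask: no rank variation to correlate")
  cd <- if (method == "fast") {
    kendall_cd(x, y)
  } else {
    sx <- sign(outer(x, x, "-"))
    sy <- sign(outer(y, y, "-"))
    sum(sx * sy) / 2
  }
  cd / (m * (m - 1) / 2)
}

#' Convert tau-a to Pearson r and Fisher z
#'
#' Uses Greiner's relation \eqn{r = \sin(\pi \tau / 2)}, the mapping
#' consistent with an underlying bivariate normal, then the Fisher
#' transform \eqn{z = \mathrm{atanh}(r)} with |r| clamped to 1 - 1e-12 so
#' perfect fits stay finite.
#'
#' @param tau Tau-a value(s) in \[-1, 1\].
#' @return List with `r` and `z` (each the same length as `tau`).
#' @export
tau_to_z <- function(tau) {
  if (any(abs(tau) > 1)) stop("|tau| > 1")
  r <- sin(pi * tau / 2)
  rc <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  list(r = r, z = atanh(rc))
}

new_group_test <- function(kind, t, df, p, d_z, n) {
  structure(list(kind = kind, t = t, df = df, p = p, d_z = d_z, n = n),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat("<group_test> ", x$kind, ": t(", x$df, ") = ", signif(x$t, 4),
      ", p = ", signif(x$p, 3), ", d_z = ", signif(x$d_z, 3), "\n", sep = "")
  invisible(x)
}

#' One-sample t test against zero (one-tailed, greater)
#'
#' Greater-than-zero model fits are assessed one-tailed because negative
#' model correlations are not interpretable as fits. Effect size is
#' \eqn{d_z = \bar{x}/s_x}.
#'
#' @param z Numeric vector of subject-level (Fisher-z) values.
#' @return A `group_test`.
#' @export
one_sample_t <- function(z) {
  n <- length(z)
  if (n < 2) stop("need at least 2 subjects")
  s <- stats::sd(z)
  if (s == 0) stop("zero variance in the tested values: ",
                   "all subjects equal ", z[1])
  tt <- stats::t.test(z, alternative = "greater")
  new_group_test("one_sample_greater", unname(tt$statistic),
                 unname(tt$parameter), tt$p.value, mean(z) / s, n)
}

#' Paired t test between two model fits (two-tailed)
#'
#' @param z1,z2 Equal-length vectors of subject-level values.
#' @return A `group_test` on the differences `z1 - z2`.
#' @export
paired_t <- function(z1, z2) {
  if (length(z1) != length(z2)) stop("paired samples differ in length")
  d <- z1 - z2
  if (length(d) < 2) stop("need at least 2 subjects")
  s <- stats::sd(d)
  if (s == 0) stop("zero variance in the paired differences")
  tt <- stats::t.test(d)
  new_group_test("paired_two_tailed", unname(tt$statistic),
                 unname(tt$parameter), tt$p.value, mean(d) / s, length(d))
}

#' Bonferroni-style alpha adjustment with half-up rounding
#'
#' `base / k`, rounded half-up to 3 decimals -- the convention that
#' reproduces printed thresholds such as 0.008 for six tests and 0.013 for
#' four.
#'
#' @param base Base alpha (default 0.05).
#' @param k Number of tests/clusters (>= 1).
#' @return Adjusted threshold.
#' @export
adjust_alpha <- function(base = 0.05, k = 1) {
  if (k < 1) stop("k must be >= 1")
  round_half_up(base / k, 3)
}

#' Noise ceiling for model fits in a region
#'
#' The lower bound is the mean (over subjects) Fisher-z tau-a correlation
#' between each subject's RDM and the group-mean RDM excluding that
#' subject; the upper bound includes the subject. The bounds bracket the
#' fit the true (unknown) model could achieve given between-subject
#' inconsistency.
#'
#' @param rdms List of subject `rdm`s (equal length).
#' @param mask A `cell_mask` restricting the cells used.
#' @return Object of class `noise_ceiling`: list with `lower`, `upper`,
#'   `mask`, `n_subjects`.
#' @export
noise_ceiling <- function(rdms, mask) {
  n <- length(rdms)
  if (n < 3) stop("need at least 3 subjects")
  M <- do.call(cbind, lapply(rdms, function(r) as.numeric(r)[mask$select]))
  grand <- rowMeans(M)
  if (length(unique(grand)) < 2)
    stop("group-mean RDM is constant over the mask")
  zlo <- zhi <- numeric(n)
  for (s in seq_len(n)) {
    others <- rowMeans(M[, -s, drop = FALSE])
    zlo[s] <- tau_to_z(tau_a(M[, s], others))$z
    zhi[s] <- tau_to_z(tau_a(M[, s], grand))$z
  }
  structure(list(lower = mean(zlo), upper = mean(zhi), mask = mask$name,
                 n_subjects = n),
            class = "noise_ceiling")
}

#' @export
print.noise_ceiling <- function(x, ...) {
  cat("<noise_ceiling> [", signif(x$lower, 3), ", ", signif(x$upper, 3),
      "] over ", x$mask, " (n = ", x$n_subjects, ")\n", sep = "")
  invisible(x)
}

#' Fit the standard model battery to a region's subject RDMs
#'
#' Builds the semantic feature, item, category and (where orthogonality
#' permits) speaker/signer identity models, fits each to every subject's
#' RDM with tau-a over the appropriate cell mask, converts to Fisher z,
#' runs the group tests and noise ceilings, and labels the region with a
#' verdict: `shared-semantic` (category structure fits both within and
#' across modality), `modality-form` (item and/or identity structure
#' without across-modality category structure), or `none`.
#'
#' @param subject_rdms List of subject `rdm`s for the region.
#' @param space A `condition_space`.
#' @param features Item x feature matrix for the semantic feature model.
#' @param provenance List describing how the ROI was defined: `selector` (a
#'   `cell_mask` of the selection statistic) and `loo` (logical; defined
#'   leave-one-participant-out). Identity models are skipped, with a note,
#'   when [orthogonality_guard()] flags them.
#' @param alpha_k Number of tests/clusters for [adjust_alpha()].
#' @param iconicity Optional named iconicity ratings; adds iconicity models
#'   on the sign-sign and across-modality masks.
#' @return Object of class `region_fit`: list with `fits` (subject-level
#'   data frame), `group` (per-model group-test data frame with ceilings),
#'   `paired` (model-comparison data frame), `alpha`, `verdict`, `notes`.
#' @export
fit_models_in_region <- function(subject_rdms, space, features,
                                 provenance = list(
                                   selector = cell_mask(space,
                                     "within_modality_combined"),
                                   loo = FALSE),
                                 alpha_k = 1, iconicity = NULL) {
  wm <- cell_mask(space, "within_modality_combined")
  xm <- cell_mask(space, "across_modality")
  sp <- cell_mask(space, "within_speech_across_speaker")
  sg <- cell_mask(space, "within_sign_across_signer")
  models <- list(
    semantic_within = semantic_feature_model(features, space, wm),
    semantic_across = semantic_feature_model(features, space, xm),
    semantic_speech = semantic_feature_model(features, space, sp),
    semantic_sign = semantic_feature_model(features, space, sg),
    category_within = category_model(
      semantic_feature_model(features, space, wm), space, wm),
    category_across = category_model(
      semantic_feature_model(features, space, xm), space, xm),
    item_within = item_model(space, wm),
    item_across = item_model(space, xm))
  notes <- character()
  for (mo in space$modalities) {
    idm <- identity_model(space, mo)
    if (orthogonality_guard(idm, provenance) == "pass") {
      models[[paste0("identity_", mo)]] <- idm
    } else {
      notes <- c(notes, paste0("identity_", mo,
        " skipped: not orthogonal to ROI selection (use leave-one-out ROIs)"))
    }
  }
  if (!is.null(iconicity)) {
    models$iconicity_sign <- iconicity_model(iconicity, space, sg)
    models$iconicity_across <- iconicity_model(iconicity, space, xm)
  }

  n <- length(subject_rdms)
  fits <- do.call(rbind, lapply(names(models), function(nm) {
    mod <- models[[nm]]
    tau <- vapply(subject_rdms, function(r) tau_a(r, mod), 0)
    conv <- tau_to_z(tau)
    data.frame(subject = seq_len(n), model = nm, mask = mod$mask$name,
               n_cells = mask_size(mod$mask), tau = tau, r = conv$r,
               z = conv$z, stringsAsFactors = FALSE)
  }))
  alpha <- adjust_alpha(0.05, alpha_k)
  group <- do.call(rbind, lapply(names(models), function(nm) {
    z <- fits$z[fits$model == nm]
    gt <- one_sample_t(z)
    nc <- noise_ceiling(subject_rdms, models[[nm]]$mask)
    data.frame(model = nm, mask = models[[nm]]$mask$name,
               n_cells = mask_size(models[[nm]]$mask),
               t = gt$t, df = gt$df, p = gt$p, d_z = gt$d_z,
               ceiling_lower = nc$lower, ceiling_upper = nc$upper,
               significant = gt$p < alpha, stringsAsFactors = FALSE)
  }))
  zof <- function(nm) fits$z[fits$model == nm]
  paired_specs <- list(
    item_within_vs_across = c("item_within", "item_across"),
    category_within_vs_across = c("category_within", "category_across"),
    semantic_speech_vs_sign = c("semantic_speech", "semantic_sign"))
  paired <- do.call(rbind, lapply(names(paired_specs), function(nm) {
    pr <- paired_specs[[nm]]
    pt <- paired_t(zof(pr[1]), zof(pr[2]))
    data.frame(comparison = nm, t = pt$t, df = pt$df, p = pt$p, d_z = pt$d_z,
               stringsAsFactors = FALSE)
  }))
  verdict <- region_verdict(group, alpha)
  structure(list(fits = fits, group = group, paired = paired, alpha = alpha,
                 verdict = verdict, notes = notes),
            class = "region_fit")
}

# decision logic over the fitted battery: category structure present both
# within and across modality -> shared semantics; item/identity structure
# without across-modality category structure -> modality-specific form
# coding; otherwise nothing interpretable survives the adjusted alpha
region_verdict <- function(group, alpha) {
  sig <- function(nm) {
    p <- group$p[group$model == nm]
    length(p) == 1 && p < alpha
  }
  if (sig("category_within") && sig("category_across")) return("shared-semantic")
  if (sig("item_within") || sig("identity_speech") || sig("identity_sign"))
    return("modality-form")
  "none"
}

#' @export
print.region_fit <- function(x, ...) {
  cat("<region_fit> verdict: ", x$verdict, " (alpha = ", x$alpha, ")\n",
      sep = "")
  print(x$group[, c("model", "t", "df", "p", "d_z", "significant")],
        row.names = FALSE, digits = 4)
  if (length(x$notes)) cat(paste0("note: ", x$notes, "\n"))
  invisible(x)
}

#' Write fit tables and group results as CSV
#'
#' @param fit A `region_fit`.
#' @param fits_path,group_path Output CSV paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_fit_tables <- function(fit, fits_path = NULL, group_path = NULL) {
  if (!is.null(fits_path))
    utils::write.csv(fit$fits, fits_path, row.names = FALSE)
  if (!is.null(group_path)) {
    g <- fit$group
    g$verdict <- fit$verdict
    utils::write.csv(g, group_path, row.names = FALSE)
  }
  invisible(c(fits_path, group_path))
}
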