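#' Amplitude presets for planted representational archetypes
#'
#' Each archetype fixes which pattern components are present in a region:
#' `shared_semantic` plants modality-invariant category structure plus
#' modality-specific item structure; `speech_form` / `sign_form` plant item
#' structure and speaker/signer identity structure in one modality only;
#' `null` plants nothing.
#'
#' The `shared_semantic` preset additionally plants an across-modality
#' item divergence (`a_item_divergent`): a modality-opposed item component
#' that raises the distance between the *same* item presented in the two
#' languages to the middle of the between-item distance distribution.
#' This encodes the signature of category-only sharing -- an item's spoken
#' and signed forms are no closer to each other than different items are
#' -- without which residual rank coupling (same-item pairs are also
#' same-category pairs) would let an item model partially inherit the
#' planted category structure across modality.
#'
#' @param archetype One of `"shared_semantic"`, `"speech_form"`,
#'   `"sign_form"`, `"null"`.
#' @param base Base pattern strength in beta units (>= 0).
#' @return List with components `a_cat`, `a_item_within` (named by
#'   modality), `a_item_shared`, `a_id` (named by modality),
#'   `a_item_divergent`.
#' @export
archetype_amplitudes <- function(archetype = c("shared_semantic", "speech_form",
                                               "sign_form", "null"),
                                 base = 1) {
  archetype <- match.arg(archetype)
  if (base < 0) stop("negative amplitude")
  z <- c(speech = 0, sign = 0)
  switch(archetype,
    shared_semantic = list(a_cat = base,
                           a_item_within = c(speech = base, sign = base),
                           a_item_shared = 0, a_id = z,
                           a_item_divergent = sqrt(0.75) * base),
    speech_form = list(a_cat = 0,
                       a_item_within = c(speech = base, sign = 0),
                       a_item_shared = 0, a_id = c(speech = base, sign = 0),
                       a_item_divergent = 0),
    sign_form = list(a_cat = 0,
                     a_item_within = c(speech = 0, sign = base),
                     a_item_shared = 0, a_id = c(speech = 0, sign = base),
                     a_item_divergent = 0),
    null = list(a_cat = 0, a_item_within = z, a_item_shared = 0, a_id = z,
                a_item_divergent = 0))
}

#' Scene configuration for the synthetic cohort generator
#'
#' Defaults emulate the study design this package targets: 17 subjects,
#' 6 runs, 36 conditions on a 3 x 3 x 4 mm voxel grid, with spatially
#' correlated noise and per-run residual frames matching what a first-level
#' GLM would leave behind.
#'
#' @param n_subjects Number of subjects (default 17).
#' @param n_runs Number of runs (default 6).
#' @param grid_dims Integer 3-vector of voxels per axis (default 24,24,16).
#' @param voxel_size Numeric 3-vector, mm (default 3,3,4).
#' @param noise_sd Per-voxel noise standard deviation in beta units.
#' @param smooth_fwhm Noise smoothing kernel FWHM in mm (0 = white noise).
#' @param n_residual_frames Residual frames per run (default 100).
#' @param subject_jitter_sd SD (log scale) of the per-subject, per-region
#'   multiplicative amplitude jitter.
#' @param base_amplitude Base planted pattern strength handed to
#'   [archetype_amplitudes()] for default regions.
#' @param regions List of regions, each a list with `name`, `archetype`,
#'   `voxels` (linear indices into the grid), and optionally `amplitudes`
#'   (defaults to `archetype_amplitudes(archetype, base_amplitude)`).
#'   `NULL` places one box region per archetype in separate grid octants.
#' @param seed Default seed recorded in the config.
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(n_subjects = 17, n_runs = 6,
                         grid_dims = c(24L, 24L, 16L),
                         voxel_size = c(3, 3, 4),
                         noise_sd = 1, smooth_fwhm = 6,
                         n_residual_frames = 100,
                         subject_jitter_sd = 0.2,
                         base_amplitude = 1,
                         regions = NULL, seed = 1L) {
  stopifnot(length(grid_dims) == 3, all(grid_dims >= 1),
            length(voxel_size) == 3, all(voxel_size > 0),
            n_runs >= 2, n_residual_frames >= 2)
  if (noise_sd <= 0) stop("non-positive noise sd")
  grid_dims <- as.integer(grid_dims)
  if (is.null(regions))
    regions <- default_regions(grid_dims, base_amplitude)
  regions <- lapply(regions, function(r) {
    if (is.null(r$amplitudes))
      r$amplitudes <- archetype_amplitudes(r$archetype, base_amplitude)
    amps <- unlist(r$amplitudes)
    if (any(amps < 0)) stop("negative amplitude in region ", r$name)
    r$voxels <- as.integer(r$voxels)
    r
  })
  vox <- unlist(lapply(regions, `[[`, "voxels"))
  if (anyDuplicated(vox)) stop("region voxel sets must be disjoint")
  if (any(vox < 1 | vox > prod(grid_dims))) stop("region voxel out of grid")
  structure(list(n_subjects = n_subjects, n_runs = n_runs,
                 grid_dims = grid_dims, voxel_size = voxel_size,
                 noise_sd = noise_sd, smooth_fwhm = smooth_fwhm,
                 n_residual_frames = n_residual_frames,
                 subject_jitter_sd = subject_jitter_sd,
                 base_amplitude = base_amplitude,
                 regions = regions, seed = as.integer(seed)),
            class = "scene_config")
}

# one box region per archetype, placed in disjoint octants of the grid
default_regions <- function(grid_dims, base_amplitude) {
  side <- pmax(1L, pmin(4L, grid_dims %/% 4L, grid_dims %/% 2L - 1L,
                        grid_dims - 1L))
  corner <- function(ox, oy, oz) {
    ix <- ox + seq_len(side[1]); iy <- oy + seq_len(side[2])
    iz <- oz + seq_len(side[3])
    g <- expand.grid(ix, iy, iz)
    as.integer(g[, 1] + (g[, 2] - 1) * grid_dims[1] +
                 (g[, 3] - 1) * grid_dims[1] * grid_dims[2])
  }
  hx <- grid_dims[1] %/% 2L; hy <- grid_dims[2] %/% 2L
  off <- 1L
  list(
    list(name = "shared_semantic", archetype = "shared_semantic",
         voxels = corner(off, off, off)),
    list(name = "speech_form", archetype = "speech_form",
         voxels = corner(hx + off, off, off)),
    list(name = "sign_form", archetype = "sign_form",
         voxels = corner(off, hy + off, off)),
    list(name = "null", archetype = "null",
         voxels = corner(hx + off, hy + off, off)))
}

#' @export
print.scene_config <- function(x, ...) {
  cat("<scene_config> ", x$n_subjects, " subjects x ", x$n_runs, " runs, grid ",
      paste(x$grid_dims, collapse = "x"), " @ ",
      paste(x$voxel_size, collapse = "x"), " mm, ",
      length(x$regions), " regions\n", sep = "")
  invisible(x)
}

#' Generate noiseless condition patterns for every region
#'
#' Builds, for each region, the 36 x V matrix of true voxel patterns
#' b(item, modality, model) = a_cat P_sem(item)
#' + a_item_within P_item^modality(item) + a_item_shared P_item(item)
#' + a_id P_id(modality, model), with every component vector drawn once
#' and then held fixed across subjects.
#'
#' Component pattern vectors are drawn from a standard normal per voxel and
#' then, when the region has at least as many voxels as components, jointly
#' orthonormalized (QR) and rescaled to norm sqrt(V). This leaves each
#' component's marginal distribution essentially unchanged for V much
#' larger than the component count, but removes the finite-voxel sampling
#' wobble of the planted geometry: every planted squared distance then
#' equals its expectation exactly (e.g., across-modality cells of a
#' shared-semantic region carry category structure and exactly zero
#' residual item structure). In tiny regions (fewer voxels than
#' components) the raw Gaussian draws are used as-is.
#'
#' The modality-invariant semantic component carries category-level
#' structure. When feature norms are supplied, each category's pattern is
#' its unit-normalized category-centroid feature vector mixed through the
#' orthonormal basis, so the planted between-category pattern distances
#' are exactly proportional to the cosine dissimilarities of the category
#' centroids (graded category similarity), while items within a category
#' share one pattern. Without norms each category gets an independent
#' basis vector (equidistant categories).
#'
#' @param config A `scene_config`.
#' @param space A `condition_space`.
#' @param seed Integer seed.
#' @param features Optional item x feature matrix (e.g., from
#'   [generate_feature_norms()]) grading the category component.
#' @return Named list (one element per region) of `n_conditions x V_region`
#'   matrices, with the region voxel indices attached as attribute
#'   `"voxels"`.
#' @export
generate_true_patterns <- function(config, space, seed = config$seed,
                                   features = NULL) {
  set.seed(seed)
  cond <- space$conditions
  n_it <- length(space$items)
  n_cat <- length(space$categories)
  n_mod <- length(space$modalities)
  Fc <- NULL
  if (!is.null(features)) {
    stopifnot(all(space$items %in% rownames(features)))
    cats <- unname(space$category_of[space$items])
    Fc <- do.call(rbind, lapply(space$categories, function(cc)
      colMeans(features[space$items[cats == cc], , drop = FALSE])))
    Fc <- Fc / sqrt(rowSums(Fc^2))
    rownames(Fc) <- space$categories
  }
  out <- list()
  for (r in config$regions) {
    V <- length(r$voxels)
    a <- r$amplitudes
    use_graded <- !is.null(Fc) &&
      V >= ncol(Fc) + n_it * (n_mod + 2) + 2 * n_mod
    n_cat_basis <- if (use_graded) ncol(Fc) else n_cat
    K <- n_cat_basis + n_it * (n_mod + 2) + 2 * n_mod
    comp <- matrix(stats::rnorm(K * V), nrow = K)
    if (V >= K) {
      Q <- qr.Q(qr(t(comp)))[, seq_len(K), drop = FALSE]
      comp <- t(Q) * sqrt(V)
    }
    take <- function(n) {
      rows <- comp[seq_len(n), , drop = FALSE]
      comp <<- comp[-seq_len(n), , drop = FALSE]
      rows
    }
    cat_rows <- if (use_graded) Fc %*% take(n_cat_basis) else take(n_cat)
    rownames(cat_rows) <- space$categories
    P_cat <- cat_rows[unname(space$category_of[space$items]), , drop = FALSE]
    rownames(P_cat) <- space$items
    P_item_mod <- lapply(stats::setNames(space$modalities, space$modalities),
                         function(m) {
                           rows <- take(n_it)
                           rownames(rows) <- space$items
                           rows
                         })
    P_item <- take(n_it)
    rownames(P_item) <- space$items
    P_div <- take(n_it)
    rownames(P_div) <- space$items
    P_id <- lapply(stats::setNames(space$modalities, space$modalities),
                   function(m) take(2))
    a_div <- if (is.null(a$a_item_divergent)) 0 else a$a_item_divergent
    tp <- matrix(0, nrow = space$n_conditions, ncol = V)
    for (k in seq_len(space$n_conditions)) {
      it <- cond$item[k]; mo <- cond$modality[k]; md <- cond$model_id[k]
      sgn <- if (mo == space$modalities[1]) 1 else -1
      tp[k, ] <- a$a_cat * P_cat[it, ] +
        a$a_item_within[[mo]] * P_item_mod[[mo]][it, ] +
        a$a_item_shared * P_item[it, ] +
        a$a_id[[mo]] * P_id[[mo]][md, ] +
        a_div * sgn * P_div[it, ]
    }
    attr(tp, "voxels") <- r$voxels
    out[[r$name]] <- tp
  }
  out
}

# separable Gaussian smoothing kernels, one row-normalized band matrix per
# axis; returns list(kernels, var_factor) where var_factor is the central
# variance reduction prod_a sum(k_a^2)
smoothing_kernels <- function(grid_dims, voxel_size, fwhm) {
  if (fwhm <= 0) return(NULL)
  sig <- fwhm / (2 * sqrt(2 * log(2))) / voxel_size   # sd in voxel units
  kernels <- vector("list", 3)
  var_factor <- 1
  for (a in 1:3) {
    d <- grid_dims[a]
    K <- outer(seq_len(d), seq_len(d),
               function(x, y) stats::dnorm(x - y, sd = max(sig[a], 1e-8)))
    K <- K / rowSums(K)
    kernels[[a]] <- K
    mid <- ceiling(d / 2)
    var_factor <- var_factor * sum(K[mid, ]^2)
  }
  list(kernels = kernels, var_factor = var_factor)
}

# n volumes of spatially correlated noise with per-voxel sd ~ noise_sd,
# returned as V x n matrix
noise_volumes <- function(n, config, kernels) {
  d <- config$grid_dims
  V <- prod(d)
  x <- matrix(stats::rnorm(V * n), nrow = V)
  if (!is.null(kernels)) {
    arr <- array(x, c(d, n))
    # axis 1
    arr <- array(kernels$kernels[[1]] %*% matrix(arr, d[1]), c(d, n))
    # axis 2
    arr <- aperm(array(kernels$kernels[[2]] %*%
                         matrix(aperm(arr, c(2, 1, 3, 4)), d[2]),
                       c(d[2], d[1], d[3], n)), c(2, 1, 3, 4))
    # axis 3
    arr <- aperm(array(kernels$kernels[[3]] %*%
                         matrix(aperm(arr, c(3, 1, 2, 4)), d[3]),
                       c(d[3], d[1], d[2], n)), c(2, 3, 1, 4))
    x <- matrix(arr, nrow = V) / sqrt(kernels$var_factor)
  }
  x * config$noise_sd
}

#' Generate one subject's run-wise betas and residual frames
#'
#' Run betas are the (subject-jittered) true patterns plus spatially
#' correlated Gaussian noise, drawn independently per run; residual frames
#' come from the identical noise process, mimicking first-level GLM
#' residuals.
#'
#' @param config A `scene_config`.
#' @param true_patterns Output of [generate_true_patterns()].
#' @param subject Subject index (used only for bookkeeping).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return An object of class `subject_data`: list with `betas` (list of
#'   `n_conditions x V` matrices, one per run), `resid` (list of
#'   `frames x V` matrices), `dims`, `voxel_size`, `subject`, `seed`.
#' @export
generate_subject <- function(config, true_patterns, subject, seed) {
  set.seed(seed)
  V <- prod(config$grid_dims)
  n_cond <- nrow(true_patterns[[1]])
  jit <- stats::rlnorm(length(true_patterns), 0, config$subject_jitter_sd)
  truth <- matrix(0, n_cond, V)
  for (k in seq_along(true_patterns)) {
    vx <- attr(true_patterns[[k]], "voxels")
    truth[, vx] <- truth[, vx] + jit[k] * true_patterns[[k]]
  }
  kern <- smoothing_kernels(config$grid_dims, config$voxel_size,
                            config$smooth_fwhm)
  betas <- vector("list", config$n_runs)
  resid <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    betas[[r]] <- truth + t(noise_volumes(n_cond, config, kern))
    resid[[r]] <- t(noise_volumes(config$n_residual_frames, config, kern))
  }
  structure(list(betas = betas, resid = resid, dims = config$grid_dims,
                 voxel_size = config$voxel_size, subject = subject,
                 seed = seed),
            class = "subject_data")
}

#' @export
print.subject_data <- function(x, ...) {
  cat("<subject_data> subject ", x$subject, ": ", length(x$betas), " runs, ",
      nrow(x$betas[[1]]), " conditions, ", ncol(x$betas[[1]]), " voxels\n",
      sep = "")
  invisible(x)
}

#' Generate a full synthetic cohort
#'
#' All subjects share one grid and one true-pattern layout; only the
#' per-subject amplitude jitter and the noise differ. Ground-truth region
#' masks are returned for recovery scoring.
#'
#' @param config A `scene_config`.
#' @param seed Integer seed (default: the config's seed).
#' @param space A `condition_space` (default: the canonical 36-condition
#'   space).
#' @param features Item x feature norms defining the graded semantic
#'   component of the planted patterns (default: synthetic norms generated
#'   from the cohort seed; the same matrix is stored in the cohort so model
#'   fitting can use it).
#' @return An object of class `cohort`: list with `subjects` (list of
#'   `subject_data`), `true_patterns`, `region_masks` (named list of voxel
#'   index vectors), `features`, `space`, `config`, `seed`.
#' @export
generate_cohort <- function(config, seed = config$seed,
                            space = build_condition_space(),
                            features = NULL) {
  if (config$n_subjects < 2) stop("need at least 2 subjects for group stats")
  if (is.null(features))
    features <- generate_feature_norms(space, seed = child_seed(seed, 77))
  tp <- generate_true_patterns(config, space, seed = child_seed(seed, 0),
                               features = features)
  subjects <- lapply(seq_len(config$n_subjects), function(s)
    generate_subject(config, tp, s, seed = child_seed(seed, s)))
  masks <- lapply(config$regions, `[[`, "voxels")
  names(masks) <- vapply(config$regions, `[[`, "", "name")
  structure(list(subjects = subjects, true_patterns = tp,
                 region_masks = masks, features = features, space = space,
                 config = config, seed = seed),
            class = "cohort")
}

#' Scene with a single planted archetype region
#'
#' Convenience wrapper around [scene_config()] placing one box region of
#' the given archetype at the grid center, the layout used for
#' parameter-recovery studies of one archetype at a time (a cohort per
#' archetype, against an otherwise empty grid).
#'
#' @param archetype Archetype name, see [archetype_amplitudes()].
#' @param grid_dims,voxel_size,n_subjects,n_runs,n_residual_frames,seed As
#'   in [scene_config()].
#' @param region_side Integer 3-vector: box side lengths in voxels.
#' @param base_amplitude Planted pattern strength (default 0.05 beta units
#'   against unit noise: moderate, paper-scale effect sizes).
#' @param ... Further arguments passed to [scene_config()].
#' @return A `scene_config` with one region named after the archetype.
#' @export
archetype_scene <- function(archetype, grid_dims = c(12L, 12L, 8L),
                            voxel_size = c(3, 3, 4), n_subjects = 17,
                            n_runs = 6, n_residual_frames = 60,
                            region_side = c(10L, 10L, 4L),
                            base_amplitude = 0.04, seed = 1L, ...) {
  lo <- pmax(1L, (grid_dims - region_side) %/% 2L + 1L)
  hi <- pmin(grid_dims, lo + region_side - 1L)
  g <- expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3])
  vox <- as.integer(g[, 1] + (g[, 2] - 1) * grid_dims[1] +
                      (g[, 3] - 1) * grid_dims[1] * grid_dims[2])
  scene_config(n_subjects = n_subjects, n_runs = n_runs,
               grid_dims = grid_dims, voxel_size = voxel_size,
               n_residual_frames = n_residual_frames,
               base_amplitude = base_amplitude,
               regions = list(list(name = archetype, archetype = archetype,
                                   voxels = vox)),
               seed = seed, ...)
}

#' @export
print.cohort <- function(x, ...) {
  cat("<cohort> ", length(x$subjects), " subjects, regions: ",
      paste(names(x$region_masks), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Generate the trial-level experimental design
#'
#' Per run: 72 core trials (two mini-blocks in which each of the 36
#' conditions appears once), 6 target fillers, 6 non-target fillers and 7
#' null trials, 91 trials in total. Core order is randomized under the
#' constraint that the same concept never occurs on consecutive trials,
#' regardless of modality; filler and null trials are interspersed at
#' uniformly random positions subject to a minimum gap of one core trial
#' between any two of them.
#'
#' @param config A `scene_config` (supplies `n_runs`).
#' @param space A `condition_space`.
#' @param seed Integer seed.
#' @param swap_modalities If `TRUE`, return the modality-swapped counterpart
#'   design (speech and sign exchanged), for paired counterbalancing.
#' @param max_retries Bounded retries for the no-repeat shuffle.
#' @return A data frame of class `design_table` with columns `run`, `trial`,
#'   `kind` (`core`, `target_filler`, `nontarget_filler`, `null`), `item`,
#'   `modality`, `model_id`, `duration_s`.
#' @export
generate_design <- function(config, space = build_condition_space(),
                            seed = config$seed, swap_modalities = FALSE,
                            max_retries = 500) {
  set.seed(seed)
  cond <- space$conditions
  dur <- c(speech = 0.558, sign = 1.107)       # mean stimulus durations, s
  n_fill <- c(target_filler = 6L, nontarget_filler = 6L, null = 7L)
  runs <- vector("list", config$n_runs)
  for (r in seq_len(config$n_runs)) {
    core <- shuffle_core_blocks(cond, max_retries, seed)
    n_core <- nrow(core)
    n_noncore <- sum(n_fill)
    n_total <- n_core + n_noncore
    # uniform positions with pairwise gap >= 2 via the stars-and-bars map
    q <- sort(sample.int(n_total - (n_noncore - 1L), n_noncore))
    noncore_pos <- q + seq_len(n_noncore) - 1L
    kinds <- sample(rep(names(n_fill), n_fill))
    fill_mod <- sample(rep(space$modalities, length.out = 12))
    tab <- data.frame(run = r, trial = seq_len(n_total), kind = "core",
                      item = NA_character_, modality = NA_character_,
                      model_id = NA_integer_, duration_s = NA_real_,
                      stringsAsFactors = FALSE)
    tab$kind[noncore_pos] <- kinds
    core_rows <- which(tab$kind == "core")
    tab$item[core_rows] <- core$item
    tab$modality[core_rows] <- core$modality
    tab$model_id[core_rows] <- core$model_id
    fi <- which(tab$kind %in% c("target_filler", "nontarget_filler"))
    tab$item[fi] <- paste0(sub("_filler", "", tab$kind[fi]), "_",
                           sample.int(18, length(fi)))
    tab$modality[fi] <- fill_mod
    tab$model_id[fi] <- sample(space$model_ids, length(fi), replace = TRUE)
    tab$duration_s <- ifelse(tab$kind == "null", 4,
                             unname(dur[tab$modality]))
    runs[[r]] <- tab
  }
  out <- do.call(rbind, runs)
  if (swap_modalities) {
    sw <- c(speech = "sign", sign = "speech")
    out$modality <- ifelse(is.na(out$modality), NA, sw[out$modality])
    out$duration_s <- ifelse(out$kind == "null", 4, unname(dur[out$modality]))
  }
  class(out) <- c("design_table", "data.frame")
  out
}

# two concatenated mini-blocks, each a permutation of all conditions, with
# no consecutive repetition of the same item (incl. the block boundary);
# each block is built by randomized greedy selection with restarts
shuffle_core_blocks <- function(cond, max_retries, seed) {
  one_block <- function(prev_item) {
    for (t in seq_len(max_retries)) {
      remaining <- seq_len(nrow(cond))
      rows <- integer(0)
      last <- prev_item
      repeat {
        cand <- remaining[!cond$item[remaining] %in% last]
        if (!length(cand)) break
        pick <- if (length(cand) == 1) cand else sample(cand, 1)
        rows <- c(rows, pick)
        remaining <- setdiff(remaining, pick)
        last <- cond$item[pick]
        if (!length(remaining)) return(rows)
      }
    }
    stop("could not satisfy the no-consecutive-item constraint after ",
         max_retries, " retries (seed ", seed, ")")
  }
  b1 <- cond[one_block(NA_character_), ]
  b2 <- cond[one_block(b1$item[nrow(b1)]), ]
  rbind(b1, b2)
}

#' Validate a design table against the design invariants
#'
#' @param design A `design_table` (or plain data frame with its columns).
#' @param space A `condition_space`.
#' @return Character vector of violations; empty when the design is valid.
#' @export
validate_design <- function(design, space = build_condition_space()) {
  bad <- character()
  for (r in unique(design$run)) {
    tab <- design[design$run == r, ]
    if (nrow(tab) != 91)
      bad <- c(bad, sprintf("run %s: %d trials, expected 91", r, nrow(tab)))
    core <- tab[tab$kind == "core", ]
    cnt <- table(paste(core$item, core$modality, core$model_id))
    if (nrow(core) != 2 * space$n_conditions || any(cnt != 2))
      bad <- c(bad, sprintf("run %s: core conditions not each presented twice", r))
    if (sum(tab$kind == "target_filler") != 6)
      bad <- c(bad, sprintf("run %s: target filler count != 6", r))
    if (sum(tab$kind == "nontarget_filler") != 6)
      bad <- c(bad, sprintf("run %s: non-target filler count != 6", r))
    if (sum(tab$kind == "null") != 7)
      bad <- c(bad, sprintf("run %s: null count != 7", r))
    consec <- which(tab$item[-1] == tab$item[-nrow(tab)] &
                      tab$kind[-1] == "core" & tab$kind[-nrow(tab)] == "core")
    if (length(consec))
      bad <- c(bad, sprintf("run %s: same concept on consecutive trials at %s",
                            r, paste(consec, collapse = ",")))
  }
  bad
}

#' Generate synthetic concept-property feature norms
#'
#' Builds a binary item x feature matrix whose induced cosine
#' dissimilarity has the block structure of feature-norm semantic models:
#' features shared within a category make within-category items similar,
#' item-unique features keep items distinct, and (optionally) features
#' shared between category pairs give the categories themselves a graded
#' similarity structure, as real property norms do. Every item receives
#' the same number of unique features, so predictions within a block are
#' exactly tied -- deliberate, since the downstream tau-a correlation
#' treats tied predictions as uninformative rather than noise.
#'
#' @param space A `condition_space`.
#' @param n_features Total number of features.
#' @param p_within_category_shared Proportion of features shared by all
#'   items of one category (including the cross-category graded block).
#' @param p_item_unique Proportion of features unique to a single item.
#'   Leftover features are global (shared by all items).
#' @param seed Integer seed (used only when `weight_range` is
#'   non-degenerate).
#' @param graded_categories If `TRUE`, about 30% of the category block is
#'   shared between category pairs in unequal proportions, grading the
#'   between-category dissimilarities.
#' @param weight_range Length-2 range for random production-frequency
#'   weights; the default `c(1, 1)` keeps the norms binary.
#' @return Numeric matrix items x features with non-negative weights.
#' @export
generate_feature_norms <- function(space, n_features = 72,
                                   p_within_category_shared = 0.5,
                                   p_item_unique = 0.5, seed = 1,
                                   graded_categories = TRUE,
                                   weight_range = c(1, 1)) {
  if (p_within_category_shared < 0 || p_within_category_shared > 1 ||
      p_item_unique < 0 || p_item_unique > 1)
    stop("proportions must lie in [0, 1]")
  if (p_within_category_shared + p_item_unique > 1)
    stop("p_within_category_shared + p_item_unique must not exceed 1")
  if (p_item_unique == 0)
    warning("p_item_unique = 0: items within a category are identical")
  items <- space$items
  cats <- unname(space$category_of[items])
  ucats <- unique(cats)
  n_cat_block <- round(n_features * p_within_category_shared)
  n_uni_block <- round(n_features * p_item_unique)
  u_per_item <- n_uni_block %/% length(items)
  cat_pairs <- if (length(ucats) > 1) utils::combn(ucats, 2) else NULL
  cross_counts <- integer(0)
  if (graded_categories && !is.null(cat_pairs) && n_cat_block > 0) {
    cross_total <- round(n_cat_block * 0.3)
    w <- rev(seq_len(ncol(cat_pairs)))
    cross_counts <- floor(cross_total * w / sum(w))
  }
  own_total <- n_cat_block - sum(cross_counts)
  own_per_cat <- own_total %/% length(ucats)

  cols <- list()
  for (cc in ucats)
    cols <- c(cols, replicate(own_per_cat, cats == cc, simplify = FALSE))
  if (length(cross_counts))
    for (k in seq_along(cross_counts))
      cols <- c(cols, replicate(cross_counts[k],
                                cats %in% cat_pairs[, k], simplify = FALSE))
  for (it in seq_along(items))
    cols <- c(cols, replicate(u_per_item, seq_along(items) == it,
                              simplify = FALSE))
  n_glob <- n_features - length(cols)
  if (n_glob > 0)
    cols <- c(cols, replicate(n_glob, rep(TRUE, length(items)),
                              simplify = FALSE))
  M <- do.call(cbind, lapply(cols, as.numeric))
  dimnames(M) <- list(items, paste0("f", seq_len(ncol(M))))
  if (diff(weight_range) > 0) {
    set.seed(seed)
    M <- M * matrix(stats::runif(ncol(M), weight_range[1], weight_range[2]),
                    length(items), ncol(M), byrow = TRUE)
  }
  M
}
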