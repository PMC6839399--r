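# independent lattice-enumeration oracle for sphere sizes
count_offsets_oracle <- function(voxel_size, radius) {
  n <- 0
  rng <- -10:10
  for (i in rng) for (j in rng) for (k in rng)
    if (sqrt((i * voxel_size[1])^2 + (j * voxel_size[2])^2 +
             (k * voxel_size[3])^2) <= radius) n <- n + 1
  n
}

test_that("sphere offsets match lattice enumeration", {
  s <- sphere_offsets(c(3, 3, 4), 8)
  expect_equal(nrow(s$offsets), 65)
  expect_equal(nrow(s$offsets), count_offsets_oracle(c(3, 3, 4), 8))
  expect_equal(nrow(sphere_offsets(c(3, 3, 3), 8)$offsets), 81)
  expect_equal(nrow(sphere_offsets(c(2, 2, 2), 0)$offsets), 1)
  # symmetric under negation, origin included, monotone in radius
  expect_true(any(rowSums(abs(s$offsets)) == 0))
  key <- do.call(paste, as.data.frame(s$offsets))
  neg <- do.call(paste, as.data.frame(-s$offsets))
  expect_setequal(key, neg)
  sizes <- vapply(seq(0, 10, by = 1), function(r)
    nrow(sphere_offsets(c(3, 3, 4), r)$offsets), 1L)
  expect_true(all(diff(sizes) >= 0))
  expect_error(sphere_offsets(c(3, 3, 4), -1), "non-negative")
})

test_that("searchlight maps agree with direct crossnobis at each center", {
  set.seed(21)
  cfg <- scene_config(n_subjects = 2, n_runs = 3, grid_dims = c(5, 5, 3),
                      n_residual_frames = 40, smooth_fwhm = 0,
                      regions = list(list(name = "r", archetype = "shared_semantic",
                                          voxels = 1:20)))
  co <- generate_cohort(cfg, seed = 3)
  su <- co$subjects[[1]]
  spec <- sphere_offsets(c(3, 3, 4), 4)
  stat <- cell_mask(co$space, "within_modality_combined")
  sm <- run_searchlight(su, spec, stat, lambda = 0.5, min_frac = 0,
                        return_rdms = TRUE)
  # oracle: rebuild the sphere at one center and use the R-level estimator
  dims <- su$dims
  center <- sm$rdm_store$centers[8]
  cz <- (center - 1) %/% (dims[1] * dims[2])
  rem <- (center - 1) %% (dims[1] * dims[2])
  cy <- rem %/% dims[1]; cx <- rem %% dims[1]
  vox <- integer(0)
  for (k in seq_len(nrow(spec$offsets))) {
    xx <- cx + spec$offsets[k, 1]; yy <- cy + spec$offsets[k, 2]
    zz <- cz + spec$offsets[k, 3]
    if (xx >= 0 && xx < dims[1] && yy >= 0 && yy < dims[2] &&
        zz >= 0 && zz < dims[3])
      vox <- c(vox, xx + yy * dims[1] + zz * dims[1] * dims[2] + 1)
  }
  cov <- estimate_noise_cov(lapply(su$resid, function(x) x[, vox]),
                            lambda = 0.5)
  want <- crossnobis_rdm(su, voxels = vox, cov = cov)
  got <- sm$rdm_store$rdms[8, ]
  expect_equal(got, as.numeric(want), tolerance = 1e-8)
  expect_equal(sm$values[center], mean(as.numeric(want)[stat$select]),
               tolerance = 1e-8)
})

test_that("searchlight maps are equivariant under grid translation", {
  sp <- build_condition_space()
  mk_cfg <- function(vox) scene_config(
    n_subjects = 2, n_runs = 2, grid_dims = c(6, 6, 3),
    n_residual_frames = 20, smooth_fwhm = 0,
    regions = list(list(name = "r", archetype = "speech_form", voxels = vox)))
  # same planted pattern placed at two x-offsets differing by 2 voxels
  v1 <- 1:4
  v2 <- v1 + 2
  spec <- sphere_offsets(c(3, 3, 4), 3.5)
  stat <- cell_mask(sp, "within_speech_across_speaker")
  tp1 <- generate_true_patterns(mk_cfg(v1), sp, seed = 5)
  tp2 <- tp1
  attr(tp2$r, "voxels") <- v2
  s1 <- generate_subject(mk_cfg(v1), tp1, 1, seed = 9)
  s2 <- generate_subject(mk_cfg(v2), tp2, 1, seed = 9)
  # identical seeds: identical noise; betas differ only by pattern placement,
  # and the map elevation follows the placement
  m1 <- run_searchlight(s1, spec, stat, lambda = 1)$values
  m2 <- run_searchlight(s2, spec, stat, lambda = 1)$values
  bg <- setdiff(which(!is.na(m1)), union(v1, v2))
  expect_gt(mean(m1[v1]), mean(m1[bg]))
  expect_gt(mean(m2[v2]), mean(m2[bg]))
})

test_that("group maps flag zero-variance voxels and respect pairing", {
  arr <- function(x) array(x, c(2, 2, 2))
  maps <- list(arr(1), arr(1), arr(1))
  gm <- group_map(maps)
  expect_true(all(is.nan(gm$values)))
  expect_equal(gm$df, 2)
  pm <- group_map(maps, test = "paired", maps2 = maps)
  expect_true(all(is.nan(pm$values)))
  expect_error(group_map(maps, test = "paired"), "maps2")
  expect_error(group_map(list(arr(1), array(1, c(2, 2, 3)))), "grid")
})

test_that("connected components follow 18-connectivity", {
  a <- array(FALSE, c(5, 5, 3))
  a[1:2, 1, 1] <- TRUE            # one compact blob
  expect_equal(length(label_components(a)), 1)
  a[4:5, 4, 3] <- TRUE            # a second, separated blob
  comps <- label_components(a)
  expect_equal(length(comps), 2)
  expect_equal(sort(lengths(comps)), c(2, 2))
  # edge-sharing voxels connect, opposite-corner voxels do not
  b <- array(FALSE, c(3, 3, 3))
  b[1, 1, 1] <- TRUE; b[2, 2, 1] <- TRUE    # edge neighbors (18-conn)
  expect_equal(length(label_components(b)), 1)
  d <- array(FALSE, c(3, 3, 3))
  d[1, 1, 1] <- TRUE; d[2, 2, 2] <- TRUE    # corner neighbors only
  expect_equal(length(label_components(d)), 2)
})

test_that("cluster inference returns an empty table without suprathreshold voxels", {
  set.seed(5)
  maps <- lapply(1:6, function(i) array(rnorm(36, sd = 1e-4), c(4, 3, 3)))
  tab <- cluster_inference(maps, n_permutations = 50, seed = 2,
                           cluster_forming_p = 1e-6)
  expect_equal(nrow(tab), 0)
  expect_s3_class(tab, "cluster_table")
})

test_that("a planted blob is recovered as a single surviving cluster", {
  set.seed(6)
  dims <- c(6, 6, 3)
  blob <- array(0, dims); blob[2:4, 2:4, 1:2] <- 1
  maps <- lapply(1:10, function(i) blob * (1 + 0.1 * rnorm(1)) +
                   array(rnorm(prod(dims), sd = 0.2), dims))
  tab <- cluster_inference(maps, n_permutations = 200, seed = 3)
  expect_gte(nrow(tab), 1)
  expect_true(tab$survives[1])
  expect_equal(tab$extent[1], sum(blob > 0))
  vox <- attr(tab, "voxels")[[1]]
  expect_setequal(vox, which(blob > 0))
})
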