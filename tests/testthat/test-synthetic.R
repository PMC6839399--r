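small_scene <- function(...) {
  args <- list(...)
  defaults <- list(n_subjects = 2, n_runs = 2, grid_dims = c(6, 6, 4),
                   n_residual_frames = 10, smooth_fwhm = 0, seed = 7)
  do.call(scene_config, utils::modifyList(defaults, args))
}

test_that("archetype presets plant the advertised components", {
  a <- archetype_amplitudes("shared_semantic", base = 2)
  expect_equal(a$a_cat, 2)
  expect_equal(unname(a$a_item_within), c(2, 2))
  expect_equal(a$a_item_shared, 0)
  expect_equal(unname(a$a_id), c(0, 0))
  sf <- archetype_amplitudes("speech_form", base = 1)
  expect_equal(unname(sf$a_item_within), c(1, 0))
  expect_equal(unname(sf$a_id), c(1, 0))
  expect_error(archetype_amplitudes("shared_semantic", base = -1), "negative")
})

test_that("null archetype yields all-zero true patterns", {
  cfg <- small_scene(regions = list(list(
    name = "null", archetype = "null", voxels = 1:40)))
  tp <- generate_true_patterns(cfg, canonical_space, seed = 1)
  expect_true(all(tp$null == 0))
})

test_that("speech-form regions plant nothing in sign conditions", {
  cfg <- small_scene(regions = list(list(
    name = "sf", archetype = "speech_form", voxels = 1:40)))
  tp <- generate_true_patterns(cfg, canonical_space, seed = 1)$sf
  sign_rows <- which(canonical_space$conditions$modality == "sign")
  D <- as.matrix(dist(tp[sign_rows, ]))
  expect_true(all(D == 0))
  speech_rows <- which(canonical_space$conditions$modality == "speech")
  expect_gt(min(dist(tp[speech_rows, ])), 0)
})

test_that("shared-semantic true patterns carry exact category geometry across modality", {
  cfg <- small_scene(regions = list(list(
    name = "ss", archetype = "shared_semantic", voxels = 1:60)))
  tp <- generate_true_patterns(cfg, canonical_space, seed = 3)$ss
  D <- as.matrix(dist(tp))^2 / ncol(tp)
  cond <- canonical_space$conditions
  xm <- cell_mask(canonical_space, "across_modality")
  pp <- pair_index(36)
  v <- D[upper.tri(D)][xm$select]
  same_cat <- (cond$category[pp[, 1]] == cond$category[pp[, 2]])[xm$select]
  same_item <- (cond$item[pp[, 1]] == cond$item[pp[, 2]])[xm$select]
  # exact level structure: one value per cell class
  expect_equal(length(unique(round(v[same_cat & !same_item], 10))), 1)
  expect_equal(length(unique(round(v[!same_cat], 10))), 1)
  expect_equal(length(unique(round(v[same_item], 10))), 1)
  # category structure: between-category exceeds within-category
  expect_gt(min(v[!same_cat]), max(v[same_cat & !same_item]))
  # no across-modality item advantage: the same item in the two languages
  # is at least as distant as different items of the same category
  expect_gte(min(v[same_item]), max(v[same_cat & !same_item]))
  # and the planted divergence keeps it inside the overall distribution
  expect_lt(max(v[same_item]), max(v[!same_cat]))
})

test_that("subject generation is deterministic and respects the noise model", {
  cfg <- small_scene()
  tp <- generate_true_patterns(cfg, canonical_space, seed = 2)
  s1 <- generate_subject(cfg, tp, 1, seed = 99)
  s2 <- generate_subject(cfg, tp, 1, seed = 99)
  expect_identical(s1$betas, s2$betas)
  expect_identical(s1$resid, s2$resid)

  # FWHM 0: voxel noise uncorrelated at lag 1 (within Monte-Carlo error)
  r <- do.call(rbind, s1$resid)
  lag1 <- cor(as.numeric(r[, 1:(ncol(r) - 1)]), as.numeric(r[, 2:ncol(r)]))
  expect_lt(abs(lag1), 0.1)

  # smoothing induces positive lag-1 correlation along x
  cfg_s <- small_scene(smooth_fwhm = 8)
  tp_s <- generate_true_patterns(cfg_s, canonical_space, seed = 2)
  s3 <- generate_subject(cfg_s, tp_s, 1, seed = 99)
  rs <- do.call(rbind, s3$resid)
  arr <- array(t(rs), c(cfg_s$grid_dims, nrow(rs)))
  x1 <- as.numeric(arr[1:5, , , ]); x2 <- as.numeric(arr[2:6, , , ])
  expect_gt(cor(x1, x2), 0.3)
})

test_that("cohorts share true patterns and reproduce bit-identically", {
  cfg <- small_scene(n_subjects = 3)
  c1 <- generate_cohort(cfg, seed = 5)
  c2 <- generate_cohort(cfg, seed = 5)
  expect_identical(c1$subjects[[2]]$betas, c2$subjects[[2]]$betas)
  expect_equal(length(c1$subjects), 3)
  expect_named(c1$region_masks,
               c("shared_semantic", "speech_form", "sign_form", "null"))
  expect_error(generate_cohort(small_scene(n_subjects = 1)), "2 subjects")
})

test_that("the trial design satisfies the run-level bookkeeping", {
  cfg <- scene_config(n_subjects = 2, n_runs = 6, grid_dims = c(4, 4, 4),
                      n_residual_frames = 10)
  des <- generate_design(cfg, canonical_space, seed = 1)
  expect_equal(validate_design(des, canonical_space), character(0))
  expect_equal(sum(des$run == 1), 91)
  core <- des[des$kind == "core", ]
  expect_equal(as.vector(table(core$item)), rep(48L, 9))
  # modality-swapped counterpart flips every core trial
  des_sw <- generate_design(cfg, canonical_space, seed = 1,
                            swap_modalities = TRUE)
  expect_equal(des_sw$modality[des$modality == "speech" & des$kind == "core"],
               rep("sign", sum(des$modality == "speech" & des$kind == "core")))
})

test_that("the design validator flags consecutive same-concept trials", {
  cfg <- small_scene(n_runs = 2)
  des <- generate_design(cfg, canonical_space, seed = 2)
  core_idx <- which(des$run == 1 & des$kind == "core")
  adj <- core_idx[which(diff(core_idx) == 1)[1]]
  bad <- des
  bad$item[adj + 1] <- bad$item[adj]   # two consecutive "orange" trials
  expect_true(any(grepl("consecutive", validate_design(bad, canonical_space))))
})

test_that("synthetic feature norms have the category block structure", {
  sp <- canonical_space
  # all category-shared: within-category dissimilarity exactly 0
  suppressWarnings(M1 <- generate_feature_norms(sp, 30, 1, 0, seed = 1))
  d1 <- semantic_feature_model(M1, sp, cell_mask(sp, "across_modality"))
  pp <- pair_index(36)
  same_cat <- sp$conditions$category[pp[, 1]] == sp$conditions$category[pp[, 2]]
  vals <- d1$values[d1$mask$select & same_cat]
  expect_true(all(abs(vals) < 1e-12))

  # all item-unique: induced model matches the item model on between-item cells
  M2 <- generate_feature_norms(sp, 27, 0, 1, seed = 1)
  xm <- cell_mask(sp, "across_modality")
  d2 <- semantic_feature_model(M2, sp, xm)
  it <- item_model(sp, xm)
  sel <- xm$select
  expect_equal(cor(d2$values[sel], it$values[sel]), 1, tolerance = 1e-10)

  # defaults: within-category < between-category dissimilarity
  M3 <- generate_feature_norms(sp, seed = 3)
  d3 <- semantic_feature_model(M3, sp, xm)
  expect_lt(mean(d3$values[sel & same_cat], na.rm = TRUE),
            mean(d3$values[sel & !same_cat], na.rm = TRUE))

  expect_warning(generate_feature_norms(sp, 30, 1, 0), "identical")
  expect_error(generate_feature_norms(sp, 30, 0.8, 0.8), "exceed")
})
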