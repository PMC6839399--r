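test_that("tau-a matches brute-force enumeration on the worked cases", {
  expect_equal(tau_a(c(1, 2, 3, 4), c(1, 3, 2, 4)), 4 / 6)
  expect_equal(tau_a(c(1, 2, 3), c(1, 1, 2)), 2 / 3)   # tied pair counts 0
  expect_equal(tau_a(c(0.3, 1.2, 5, 9), c(0.3, 1.2, 5, 9)), 1)
  expect_error(tau_a(c(1, 2, 3), c(2, 2, 2)), "constant")
  expect_error(tau_a(c(1, 2), c(1, 2)), "3 cells")
})

test_that("the merge-sort fast path agrees exactly with brute force", {
  set.seed(31)
  for (rep in 1:400) {
    m <- sample(3:40, 1)
    x <- sample(0:5, m, replace = TRUE) + ifelse(runif(m) < 0.5, 0, 0.25)
    y <- sample(0:4, m, replace = TRUE)
    if (length(unique(y)) < 2) y[1] <- y[1] + 1
    if (length(unique(x)) < 2) x[1] <- x[1] + 1
    expect_identical(tau_a(x, y, method = "fast"),
                     tau_a(x, y, method = "brute"))
  }
})

test_that("tau converts to r and z by Greiner's relation with clamping", {
  expect_equal(tau_to_z(0), list(r = 0, z = 0))
  conv <- tau_to_z(0.5)
  expect_equal(conv$r, sin(pi * 0.25))
  expect_equal(round(conv$r, 5), 0.70711)
  expect_equal(round(conv$z, 5), 0.88137)
  at1 <- tau_to_z(1)
  expect_equal(at1$r, 1)
  expect_true(is.finite(at1$z))
  expect_equal(at1$z, atanh(1 - 1e-12))
  expect_error(tau_to_z(1.2), "tau")
  # odd and strictly increasing
  taus <- seq(-0.99, 0.99, length.out = 41)
  z <- tau_to_z(taus)$z
  expect_equal(z, -rev(z), tolerance = 1e-12)
  expect_true(all(diff(z) > 0))
})

test_that("group t tests reproduce hand arithmetic and guard degeneracy", {
  gt <- one_sample_t(c(1, 2, 3))
  expect_equal(gt$t, 2 / (1 / sqrt(3)), tolerance = 1e-6)
  expect_equal(round(gt$t, 4), 3.4641)
  expect_equal(gt$df, 2)
  expect_equal(gt$d_z, 2)
  expect_error(one_sample_t(rep(0.5, 4)), "zero variance")

  set.seed(8)
  half <- rnorm(1000)
  sym <- c(half, -half)    # exactly symmetric about 0
  expect_equal(one_sample_t(sym)$p, 0.5, tolerance = 1e-10)

  pt <- paired_t(c(2, 4, 6), c(1, 2, 3))
  expect_equal(round(abs(pt$t), 4), 3.4641)
  pt_swap <- paired_t(c(1, 2, 3), c(2, 4, 6))
  expect_equal(pt_swap$t, -pt$t)
  expect_equal(pt_swap$p, pt$p)
  expect_error(paired_t(c(1, 2), c(1, 2, 3)), "length")
  expect_error(paired_t(c(1, 2, 3), c(1, 2, 3)), "zero variance")
})

test_that("one-sample test rejects at the nominal rate under the null", {
  set.seed(99)
  reps <- 2000
  rej <- mean(replicate(reps, one_sample_t(rnorm(12))$p < 0.05))
  expect_lt(abs(rej - 0.05), 0.015)
})

test_that("alpha adjustment reproduces the printed thresholds", {
  expect_equal(adjust_alpha(0.05, 6), 0.008)
  expect_equal(adjust_alpha(0.05, 3), 0.017)
  expect_equal(adjust_alpha(0.05, 4), 0.013)
  expect_equal(adjust_alpha(0.05, 5), 0.010)
  expect_equal(adjust_alpha(0.05, 1), 0.050)
  expect_error(adjust_alpha(0.05, 0), "k")
})

test_that("noise ceilings bracket achievable fits", {
  sp <- canonical_space
  mask <- cell_mask(sp, "within_modality_combined")
  base <- new_rdm_for_test(seq_len(630) / 630)
  # identical subjects: tau = 1 for both bounds, clamped z equal
  nc <- noise_ceiling(list(base, base, base), mask)
  expect_equal(nc$lower, nc$upper)
  expect_equal(nc$lower, atanh(1 - 1e-12))
  expect_equal(nc$n_subjects, 3)
  # signal + noise: lower <= upper over repeated cohorts
  set.seed(12)
  ok <- replicate(40, {
    sig <- rnorm(630)
    rdms <- lapply(1:6, function(i) new_rdm_for_test(sig + rnorm(630, sd = 2)))
    c0 <- noise_ceiling(rdms, mask)
    c0$lower <= c0$upper
  })
  expect_true(all(ok))
  # pure noise: the leave-one-out lower bound is unbiased near zero; the
  # inclusive upper bound retains the well-known small positive bias from
  # each subject's own contribution to the grand mean
  set.seed(13)
  vals <- replicate(60, {
    rdms <- lapply(1:5, function(i) new_rdm_for_test(rnorm(630)))
    unlist(noise_ceiling(rdms, mask)[c("lower", "upper")])
  })
  se <- sd(vals[1, ]) / sqrt(ncol(vals))
  expect_lt(abs(mean(vals[1, ])), 3 * se + 0.02)
  expect_gt(mean(vals[2, ]), 0)
  expect_true(all(vals[1, ] <= vals[2, ]))
  expect_error(noise_ceiling(list(base, base), mask), "3 subjects")
  flat <- new_rdm_for_test(rep(1, 630))
  expect_error(noise_ceiling(list(flat, flat, flat), mask), "constant")
})

test_that("region fitting recovers a null region as verdict none", {
  sp <- canonical_space
  set.seed(77)
  # subject RDMs that are pure estimator noise
  rdms <- lapply(1:10, function(i) new_rdm_for_test(rnorm(630, sd = 0.05)))
  F <- generate_feature_norms(sp, seed = 6)
  fit <- fit_models_in_region(rdms, sp, F,
                              provenance = list(
                                selector = cell_mask(sp, "within_modality_combined"),
                                loo = TRUE))
  expect_s3_class(fit, "region_fit")
  expect_equal(fit$verdict, "none")
  expect_true(all(c("identity_speech", "identity_sign") %in% fit$group$model))
})

test_that("identity models are withheld from same-data ROIs", {
  sp <- canonical_space
  set.seed(78)
  rdms <- lapply(1:6, function(i) new_rdm_for_test(rnorm(630)))
  F <- generate_feature_norms(sp, seed = 6)
  fit <- fit_models_in_region(rdms, sp, F,
                              provenance = list(
                                selector = cell_mask(sp, "within_modality_combined"),
                                loo = FALSE))
  expect_false(any(grepl("identity", fit$group$model)))
  expect_true(any(grepl("identity", fit$notes)))
})
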