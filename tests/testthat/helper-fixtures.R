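# shared fixtures: built in code, deliberately tiny

canonical_space <- build_condition_space()

# a reduced space for unit tests: 3 items, one category, relaxed checks
tiny_space <- build_condition_space(
  items = c("a", "b", "c"),
  category_of = c(a = "x", b = "x", c = "x"),
  relaxed = TRUE)

# minimal subject with hand-set betas: `diffs` gives per-run pattern
# difference between conditions 1 and 2 over P voxels
two_cond_subject <- function(diffs, n_voxels = length(diffs[[1]]),
                             n_frames = 8) {
  betas <- lapply(diffs, function(d) rbind(d, rep(0, n_voxels)))
  resid <- replicate(length(diffs),
                     matrix(stats::rnorm(n_frames * n_voxels), n_frames),
                     simplify = FALSE)
  structure(list(betas = betas, resid = resid,
                 dims = c(n_voxels, 1L, 1L), voxel_size = c(3, 3, 4),
                 subject = 1, seed = NA),
            class = "subject_data")
}

identity_cov <- function(P) {
  structure(list(sigma = diag(P), lambda = 0, n_runs = 1),
            class = "noise_cov")
}

# small random subject for property tests
random_subject <- function(n_cond = 6, V = 10, R = 3, frames = 25, sd = 1,
                           seed = 1) {
  set.seed(seed)
  structure(list(
    betas = replicate(R, matrix(rnorm(n_cond * V, sd = sd), n_cond),
                      simplify = FALSE),
    resid = replicate(R, matrix(rnorm(frames * V, sd = sd), frames),
                      simplify = FALSE),
    dims = c(V, 1L, 1L), voxel_size = c(3, 3, 4), subject = 1, seed = seed),
    class = "subject_data")
}

# an rdm object over the canonical 36 conditions from raw cell values
new_rdm_for_test <- function(values) {
  structure(values, n_conditions = 36L, class = "rdm")
}

# brute-force crossnobis straight from the defining formula, as an
# independent oracle for the vectorized/compiled paths
crossnobis_oracle <- function(betas, sigma_inv) {
  R <- length(betas)
  n <- nrow(betas[[1]])
  P <- ncol(betas[[1]])
  D <- matrix(0, n, n)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    acc <- 0
    for (m in 1:R) for (k in 1:R) {
      if (m == k) next
      dm <- betas[[m]][i, ] - betas[[m]][j, ]
      dk <- betas[[k]][i, ] - betas[[k]][j, ]
      acc <- acc + drop(dm %*% sigma_inv %*% dk)
    }
    D[i, j] <- acc / (P * R * (R - 1))
  }
  D[upper.tri(D)]
}
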