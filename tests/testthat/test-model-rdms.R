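test_that("semantic feature model is cosine distance tiled over cells", {
  sp <- tiny_space
  F <- rbind(a = c(1, 1, 0), b = c(1, 0, 0), c = c(0, 0, 1))
  mask <- cell_mask(sp, "across_modality")
  m <- semantic_feature_model(F, sp, mask)
  pp <- pair_index(sp$n_conditions)
  val_of <- function(i1, i2) {
    k <- which(sp$conditions$item[pp[, 1]] == i1 &
                 sp$conditions$item[pp[, 2]] == i2 & mask$select)[1]
    m$values[k]
  }
  expect_equal(val_of("a", "b"), 1 - 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(val_of("a", "c"), 1)
  expect_equal(val_of("b", "c"), 1)
  expect_equal(val_of("a", "a"), 0)   # identical vectors
  expect_error(semantic_feature_model(rbind(a = 0, b = 1, c = 1) %*% t(c(1, 1)),
                                      sp, mask), "zero feature vector")
})

test_that("item model predicts uniqueness with the enumerated cell counts", {
  sp <- canonical_space
  ws <- cell_mask(sp, "within_speech_across_speaker")
  m <- item_model(sp, ws)
  expect_equal(sum(m$values[m$mask$select] == 0), 9)
  expect_equal(sum(m$values[m$mask$select] == 1), 72)
  xm <- cell_mask(sp, "across_modality")
  mx <- item_model(sp, xm)
  expect_equal(sum(mx$values[mx$mask$select] == 0), 36)
  expect_equal(sum(mx$values[mx$mask$select] == 1), 288)
  # a mask with no same-item cells gives a constant, unusable model
  sp1 <- build_condition_space(items = "z", category_of = c(z = "x"),
                               relaxed = TRUE)
  expect_warning(item_model(sp1, cell_mask(sp1, "across_modality")),
                 "constant")
})

test_that("the category model drops same-item cells and keeps feature predictions", {
  sp <- canonical_space
  F <- generate_feature_norms(sp, seed = 2)
  for (sel in c("within_speech_across_speaker", "across_modality")) {
    mask <- cell_mask(sp, sel)
    fm <- semantic_feature_model(F, sp, mask)
    cm <- category_model(fm, sp, mask)
    n_same <- if (sel == "across_modality") 36 else 9
    expect_equal(mask_size(cm$mask), mask_size(mask) - n_same)
    pp <- pair_index(36)
    same_item <- sp$conditions$item[pp[, 1]] == sp$conditions$item[pp[, 2]]
    expect_false(any(cm$mask$select & same_item))
    sel_cells <- cm$mask$select
    expect_equal(cm$values[sel_cells], fm$values[sel_cells])
  }
})

test_that("identity models cover all within-modality cells of one modality", {
  sp <- canonical_space
  for (mo in c("speech", "sign")) {
    m <- identity_model(sp, mo)
    expect_equal(mask_size(m$mask), 153)
    expect_equal(sum(m$values[m$mask$select] == 0), 2 * choose(9, 2))
    expect_equal(sum(m$values[m$mask$select] == 1), 81)
  }
  expect_error(identity_model(sp, "gesture"), "unknown modality")
})

test_that("iconicity model is the absolute rating difference", {
  sp <- tiny_space
  mask <- cell_mask(sp, "within_sign_across_signer")
  r <- c(a = 3.80, b = 4.23, c = 4.23)
  m <- iconicity_model(r, sp, mask)
  vals <- m$values[m$mask$select]
  expect_setequal(round(unique(vals), 10), c(0, 0.43))
  m2 <- iconicity_model(c(a = 1, b = 7, c = 4), sp, mask)
  expect_equal(max(m2$values, na.rm = TRUE), 6)
  expect_warning(iconicity_model(c(a = 0.5, b = 4, c = 4), sp, mask),
                 "1-7 scale")
})

test_that("normalized Levenshtein distance matches the dynamic-programming oracle", {
  tr <- list(bus = c("b", "V", "s"),
             train = c("t", "r", "eI", "n"),
             mouse = c("m", "aU", "s"),
             monkey = c("m", "V", "N", "k", "i"))
  D <- levenshtein_phon_distance(tr)
  expect_equal(D["bus", "train"], 1.0)          # 4 edits / 4 phonemes
  expect_equal(D["mouse", "monkey"], 0.8)       # 4 edits / 5 phonemes
  expect_equal(diag(D), rep(0, 4), ignore_attr = TRUE)
  expect_equal(D, t(D))
  # cross-check against the generalized edit distance in base R, mapping
  # each phoneme symbol to one character
  syms <- unique(unlist(tr))
  enc <- vapply(tr, function(x)
    paste(letters[match(x, syms)], collapse = ""), "")
  expect_equal(unname(D["train", "monkey"]),
               unname(utils::adist(enc["train"], enc["monkey"])[1, 1]) / 5)
  expect_error(levenshtein_phon_distance(list(a = character(0))), "empty")
})

test_that("model correlation screens over shared cells", {
  sp <- canonical_space
  xm <- cell_mask(sp, "across_modality")
  im <- item_model(sp, xm)
  expect_equal(model_correlation(im, im)$r, 1)
  flipped <- im
  flipped$values <- 1 - im$values
  cc <- model_correlation(im, flipped)
  expect_equal(cc$r, -1)
  expect_equal(cc$n, 324)
  # two independently generated item-level measures correlate weakly
  set.seed(4)
  rand_item_dist <- function() {
    M <- matrix(0, 9, 9)
    M[upper.tri(M)] <- runif(36)
    M + t(M)
  }
  r_obs <- replicate(60, model_correlation(rand_item_dist(),
                                           rand_item_dist())$r)
  expect_equal(model_correlation(rand_item_dist(), rand_item_dist())$n, 36)
  expect_lt(abs(mean(r_obs)), 2 / sqrt(36))
})

test_that("model RDMs decompose into item and category components", {
  sp <- canonical_space
  F <- generate_feature_norms(sp, seed = 5)
  xm <- cell_mask(sp, "across_modality")
  fm <- semantic_feature_model(F, sp, xm)
  cm <- category_model(fm, sp, xm)
  im <- item_model(sp, xm)
  # on different-item cells the feature model ranks exactly as the category model
  sel <- cm$mask$select
  expect_equal(rank(fm$values[sel]), rank(cm$values[sel]))
  # the same-vs-different-item contrast of the feature model matches the item model
  sel_all <- fm$mask$select
  pp <- pair_index(36)
  same <- sp$conditions$item[pp[, 1]] == sp$conditions$item[pp[, 2]]
  expect_true(all(fm$values[sel_all & same] <
                    min(fm$values[sel_all & !same])))
  expect_true(all(im$values[sel_all & same] == 0))
})

test_that("model RDMs round-trip as square CSV with sidecar", {
  sp <- canonical_space
  m <- item_model(sp, cell_mask(sp, "across_modality"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_model_rdm(m, path)
  sq <- as.matrix(utils::read.csv(path))
  expect_equal(dim(sq), c(36, 36))
  expect_equal(sum(!is.na(sq[upper.tri(sq)])), 324)
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$name, "item")
})
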