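new_model_rdm <- function(values, mask, name) {
  stopifnot(inherits(mask, "cell_mask"), length(values) == length(mask$select))
  values[!mask$select] <- NA_real_
  structure(list(values = values, mask = mask, name = name),
            class = "model_rdm")
}

#' @export
print.model_rdm <- function(x, ...) {
  cat("<model_rdm> ", x$name, " over ", x$mask$name, " (",
      mask_size(x$mask), " cells)\n", sep = "")
  invisible(x)
}

# item-pair dissimilarity tiled over the masked cells of a space
tile_item_dissim <- function(item_dissim, space, mask, name) {
  pp <- pair_index(space$n_conditions)
  it_i <- space$conditions$item[pp[, "i"]]
  it_j <- space$conditions$item[pp[, "j"]]
  vals <- item_dissim[cbind(it_i, it_j)]
  new_model_rdm(vals, mask, name)
}

#' Semantic feature model RDM
#'
#' Item-pair dissimilarity is the cosine distance between the items'
#' feature vectors (e.g., concept property norms weighted by production
#' frequency), tiled over every masked cell by the items of its two
#' conditions; cells whose two conditions share an item get 0. Only the
#' rank order of the predictions matters downstream (tau-a fitting).
#'
#' @param features Numeric `item x feature` matrix with rownames matching
#'   the space's items.
#' @param space A `condition_space`.
#' @param mask A `cell_mask` giving the tested cells.
#' @return A `model_rdm` named `"semantic_feature"`.
#' @export
semantic_feature_model <- function(features, space, mask) {
  stopifnot(all(space$items %in% rownames(features)))
  F <- features[space$items, , drop = FALSE]
  nrm <- sqrt(rowSums(F^2))
  if (any(nrm == 0))
    stop("zero feature vector for item(s): ",
         paste(space$items[nrm == 0], collapse = ", "))
  cosang <- (F %*% t(F)) / outer(nrm, nrm)
  D <- 1 - cosang
  diag(D) <- 0
  tile_item_dissim(D, space, mask, "semantic_feature")
}

#' Item model RDM
#'
#' Predicts that each item is uniquely represented: cells whose conditions
#' share an item are 0, all other cells 1. Carries no between-item
#' (category) structure.
#'
#' @inheritParams semantic_feature_model
#' @return A `model_rdm` named `"item"`.
#' @export
item_model <- function(space, mask) {
  n_it <- length(space$items)
  D <- 1 - diag(n_it)
  dimnames(D) <- list(space$items, space$items)
  m <- tile_item_dissim(D, space, mask, "item")
  if (all(m$values[m$mask$select] == m$values[m$mask$select][1]))
    warning("item model is constant over this mask (no same-item cells); ",
            "unusable for rank correlation")
  m
}

#' Category model RDM
#'
#' The between-item component of the semantic feature model: predictions
#' are copied from the feature model but same-item cells are removed from
#' the tested mask, so the model carries category structure only.
#'
#' @param feature_model A `model_rdm` from [semantic_feature_model()].
#' @inheritParams semantic_feature_model
#' @return A `model_rdm` named `"category"` over the reduced mask.
#' @export
category_model <- function(feature_model, space, mask) {
  pp <- pair_index(space$n_conditions)
  same_item <- space$conditions$item[pp[, "i"]] ==
    space$conditions$item[pp[, "j"]]
  sub_mask <- mask
  sub_mask$select <- mask$select & !same_item
  sub_mask$name <- paste0(mask$name, "_between_item")
  vals <- feature_model$values
  if (any(sub_mask$select & is.na(vals)))
    stop("feature model does not cover all between-item cells of the mask")
  new_model_rdm(vals, sub_mask, "category")
}

#' Speaker/signer identity model RDM
#'
#' Over all within-modality cells of one modality (including same-speaker
#' pairs), predicts larger distances between tokens from different
#' speakers/signers (1) than from the same speaker/signer (0). Restricted
#' to across-speaker cells only, the model would be constant and
#' unfittable, which is why its mask must include the same-speaker cells
#' and why testing it requires selection-independent (leave-one-out) ROIs.
#'
#' @param space A `condition_space`.
#' @param modality `"speech"` or `"sign"`.
#' @return A `model_rdm` named `"identity_<modality>"`.
#' @export
identity_model <- function(space, modality) {
  if (!modality %in% space$modalities) stop("unknown modality: ", modality)
  mask <- cell_mask(space, "within_modality_all", modality = modality)
  pp <- pair_index(space$n_conditions)
  vals <- as.numeric(space$conditions$model_id[pp[, "i"]] !=
                       space$conditions$model_id[pp[, "j"]])
  new_model_rdm(vals, mask, paste0("identity_", modality))
}

#' Iconicity model RDM
#'
#' Predicted dissimilarity between two conditions is the absolute
#' difference of their items' iconicity ratings (1 = low, 7 = high).
#'
#' @param ratings Named numeric vector, one rating per item, on a 1-7 scale.
#' @inheritParams semantic_feature_model
#' @return A `model_rdm` named `"iconicity"`.
#' @export
iconicity_model <- function(ratings, space, mask) {
  stopifnot(all(space$items %in% names(ratings)))
  r <- ratings[space$items]
  if (any(r < 1 | r > 7))
    warning("iconicity ratings outside the 1-7 scale")
  D <- abs(outer(r, r, "-"))
  dimnames(D) <- list(space$items, space$items)
  tile_item_dissim(D, space, mask, "iconicity")
}

#' Normalized Levenshtein distance between phoneme sequences
#'
#' The number of phoneme insertions, deletions and/or substitutions needed
#' to turn one sequence into the other, divided by the length of the longer
#' sequence. Used as a phonological-distance screen for candidate models.
#'
#' @param transcriptions Named list, one character vector of phoneme
#'   symbols per item.
#' @return Symmetric item x item matrix of distances in \[0, 1\]; 0 iff the
#'   sequences are identical.
#' @export
levenshtein_phon_distance <- function(transcriptions) {
  if (any(lengths(transcriptions) == 0)) stop("empty phoneme sequence")
  n <- length(transcriptions)
  D <- matrix(0, n, n, dimnames = list(names(transcriptions),
                                       names(transcriptions)))
  for (a in seq_len(n - 1)) for (b in (a + 1):n) {
    x <- transcriptions[[a]]; y <- transcriptions[[b]]
    ed <- edit_distance(x, y) / max(length(x), length(y))
    D[a, b] <- ed; D[b, a] <- ed
  }
  D
}

# plain dynamic-programming edit distance over symbol vectors
edit_distance <- function(x, y) {
  nx <- length(x); ny <- length(y)
  prev <- 0:ny
  for (i in seq_len(nx)) {
    cur <- numeric(ny + 1)
    cur[1] <- i
    for (j in seq_len(ny)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[ny + 1]
}

#' Cosine dissimilarity between item feature vectors
#'
#' The item-level distance matrix underlying the semantic feature model,
#' exposed for confound screening against other item-pair measures.
#'
#' @param features Item x feature matrix.
#' @return Symmetric item x item cosine-distance matrix.
#' @export
cosine_dissim <- function(features) {
  nrm <- sqrt(rowSums(features^2))
  if (any(nrm == 0)) stop("zero feature vector")
  D <- 1 - (features %*% t(features)) / outer(nrm, nrm)
  diag(D) <- 0
  D
}

#' Pearson correlation between two candidate models
#'
#' Used to screen candidate models for confounds (e.g., checking that a
#' phonological-distance model does not correlate with the semantic
#' feature distances). Accepts either two `model_rdm`s (correlated over
#' the intersection of their tested-cell masks) or two symmetric
#' item x item distance matrices (correlated over the unordered item
#' pairs, e.g., n = 36 pairs for 9 items).
#'
#' @param a,b `model_rdm` objects over the same condition space, or
#'   square item-level distance matrices of the same dimension.
#' @return List with `r`, `n` (shared cells or item pairs), `p`
#'   (two-tailed).
#' @export
model_correlation <- function(a, b) {
  if (is.matrix(a) && is.matrix(b)) {
    stopifnot(nrow(a) == ncol(a), all(dim(a) == dim(b)))
    x <- a[upper.tri(a)]
    y <- b[upper.tri(b)]
  } else {
    shared <- a$mask$select & b$mask$select
    if (sum(shared) < 3) stop("fewer than 3 shared cells between the masks")
    x <- a$values[shared]
    y <- b$values[shared]
  }
  if (length(x) < 3) stop("fewer than 3 shared cells between the masks")
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), n = length(x), p = ct$p.value)
}

#' Write / read a model RDM as a square CSV with a JSON sidecar
#'
#' Untested cells are written as `NA`; the sidecar records the model name
#' and mask name.
#'
#' @param model A `model_rdm`.
#' @param path CSV path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_model_rdm <- function(model, path) {
  n <- model$mask$n_conditions
  m <- squareform(model$values, n, diag = NA)
  utils::write.csv(m, path, row.names = FALSE)
  jsonlite::write_json(list(name = model$name, mask = model$mask$name),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
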