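#' Default stimulus set: nine items in three semantic categories
#'
#' @return Named character vector mapping item to category.
#' @export
default_items <- function() {
  c(orange = "fruit", grapes = "fruit", apple = "fruit",
    mouse = "animals", lion = "animals", monkey = "animals",
    train = "transport", bus = "transport", bicycle = "transport")
}

#' Build the condition space of an item x modality x speaker/signer design
#'
#' Each item is presented in two modalities (speech, sign), each produced by
#' one of two language models (speakers for speech, signers for sign). The
#' canonical condition order is modality-major (all speech conditions before
#' all sign conditions), then model id, then item, so that the 9 x 9 item
#' sub-blocks of an RDM are contiguous.
#'
#' @param items Character vector of item labels (default: the nine-item set
#'   from [default_items()]).
#' @param category_of Named character vector mapping each item to its
#'   category. Defaults to [default_items()].
#' @param relaxed If `TRUE`, skip the 9-item / 3-per-category design checks
#'   (useful for reduced unit-test spaces); items must still be distinct and
#'   covered by `category_of`.
#' @return An object of class `condition_space`: a list with `items`,
#'   `categories`, `modalities`, `model_ids`, and `conditions` (a data frame
#'   with columns `item`, `category`, `modality`, `model_id`,
#'   `canonical_index`).
#' @export
build_condition_space <- function(items = names(default_items()),
                                  category_of = default_items(),
                                  relaxed = FALSE) {
  if (anyDuplicated(items)) stop("duplicate item labels")
  if (!relaxed && length(items) != 9)
    stop("expected exactly 9 items, got ", length(items))
  if (!all(items %in% names(category_of)))
    stop("every item needs a category in `category_of`")
  category_of <- category_of[items]
  if (!relaxed) {
    tab <- table(category_of)
    if (length(tab) != 3 || any(tab != 3))
      stop("expected 3 categories with exactly 3 items each")
  }
  modalities <- c("speech", "sign")
  model_ids <- c(1L, 2L)
  conditions <- expand.grid(item = items, model_id = model_ids,
                            modality = modalities,
                            KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  # expand.grid varies the first factor fastest: item, then model_id, then
  # modality -- exactly the canonical modality-major order.
  conditions$category <- unname(category_of[conditions$item])
  conditions$canonical_index <- seq_len(nrow(conditions))
  conditions <- conditions[, c("item", "category", "modality", "model_id",
                               "canonical_index")]
  structure(
    list(items = items,
         categories = unique(unname(category_of)),
         category_of = category_of,
         modalities = modalities,
         model_ids = model_ids,
         conditions = conditions,
         n_conditions = nrow(conditions)),
    class = "condition_space")
}

#' @export
print.condition_space <- function(x, ...) {
  cat("<condition_space> ", x$n_conditions, " conditions: ",
      length(x$items), " items x ", length(x$modalities), " modalities x ",
      length(x$model_ids), " models\n", sep = "")
  invisible(x)
}

#' Number of unordered condition pairs in a space
#' @param space A `condition_space`.
#' @return Integer pair count.
#' @export
n_pairs <- function(space) {
  n <- space$n_conditions
  n * (n - 1L) / 2L
}

#' Select a named subset of RDM cells
#'
#' Cell masks are boolean indicators over unordered condition pairs (the
#' upper triangle of the RDM). The named selectors isolate the blocks used
#' by the analysis: within-modality distances are restricted to pairs from
#' *different* speakers/signers so that low-level perceptual similarity
#' between tokens from the same person cannot drive them; the identity
#' models additionally need the same-speaker/signer pairs, provided by
#' `within_modality_all`.
#'
#' @param space A `condition_space`.
#' @param selector One of `"within_speech_across_speaker"`,
#'   `"within_sign_across_signer"`, `"within_modality_combined"`,
#'   `"across_modality"`, `"within_modality_all"`.
#' @param modality For `"within_modality_all"`, which modality
#'   (`"speech"` or `"sign"`).
#' @return An object of class `cell_mask`: list with `name`, logical
#'   `select` over pairs, and the space's condition count.
#' @export
cell_mask <- function(space,
                      selector = c("within_speech_across_speaker",
                                   "within_sign_across_signer",
                                   "within_modality_combined",
                                   "across_modality",
                                   "within_modality_all"),
                      modality = NULL) {
  selector <- match.arg(selector)
  cond <- space$conditions
  pp <- pair_index(space$n_conditions)
  mod_i <- cond$modality[pp[, "i"]]; mod_j <- cond$modality[pp[, "j"]]
  mdl_i <- cond$model_id[pp[, "i"]]; mdl_j <- cond$model_id[pp[, "j"]]
  sel <- switch(
    selector,
    within_speech_across_speaker =
      mod_i == "speech" & mod_j == "speech" & mdl_i != mdl_j,
    within_sign_across_signer =
      mod_i == "sign" & mod_j == "sign" & mdl_i != mdl_j,
    within_modality_combined =
      mod_i == mod_j & mdl_i != mdl_j,
    across_modality = mod_i != mod_j,
    within_modality_all = {
      if (is.null(modality) || !modality %in% space$modalities)
        stop("within_modality_all needs modality = \"speech\" or \"sign\"")
      mod_i == modality & mod_j == modality
    })
  name <- if (selector == "within_modality_all")
    paste0("within_modality_all_", modality) else selector
  structure(list(name = name, select = sel, n_conditions = space$n_conditions),
            class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat("<cell_mask> ", x$name, ": ", sum(x$select), "/", length(x$select),
      " cells\n", sep = "")
  invisible(x)
}

#' Number of cells selected by a mask
#' @param mask A `cell_mask`.
#' @return Integer.
#' @export
mask_size <- function(mask) sum(mask$select)

#' Write / read a condition table as CSV
#'
#' @param space A `condition_space`.
#' @param path File path.
#' @return `write_condition_table` returns `path` invisibly;
#'   `read_condition_table` returns the condition data frame (canonical
#'   order restored via the `canonical_index` column).
#' @export
write_condition_table <- function(space, path) {
  utils::write.csv(space$conditions, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_condition_table
#' @export
read_condition_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("item", "category", "modality", "model_id", "canonical_index")
  if (!all(need %in% names(tab)))
    stop("condition table missing columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab[order(tab$canonical_index), need]
}
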