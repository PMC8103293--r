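# Stratified minority-driven cross-validation plan: the fold count equals
# the number of label-1 children; each test fold holds exactly one child of
# each label, so when label-0 children are fewer than folds, the first few
# (in seed-permuted order) are reused in a second test fold.

#' Build the stratified fold plan
#'
#' Fold count = size of the larger class (with 49 label-1 and 46 label-0
#' children this is 49-fold cross-validation). Each class is permuted by
#' seed and assigned to test folds cyclically, so every child is tested at
#' least once and the first `|n1 - n0|` children of the smaller class (by
#' permuted order) appear in exactly two test folds. Training rows of a
#' fold are all children outside its test pair.
#'
#' @param labels Tibble (or data frame) with columns `id` and `label`
#'   (0/1); typically a feature table.
#' @param seed Integer seed making the plan deterministic.
#' @return A `fold_plan`: list with `folds` (tibble `fold`, `test_pos`,
#'   `test_neg`), `reuse_ids` (ids of the smaller class used twice),
#'   `ids`, `labels`.
#' @examples
#' labs <- tibble::tibble(id = paste0("c", 1:7), label = c(1, 1, 1, 1, 0, 0, 0))
#' build_fold_plan(labs, seed = 1)
#' @export
build_fold_plan <- function(labels, seed = 1L) {
  labels <- dplyr::distinct(tibble::as_tibble(labels)[, c("id", "label")])
  if (anyDuplicated(labels$id)) stop("conflicting labels for the same id")
  pos <- labels$id[labels$label == 1]
  neg <- labels$id[labels$label == 0]
  if (length(pos) == 0 || length(neg) == 0) {
    stop("both labels must be present to build a stratified plan")
  }
  withr::with_seed(seed, {
    pos <- sample(pos)
    neg <- sample(neg)
  })
  n1 <- length(pos); n0 <- length(neg)
  k <- max(n1, n0)
  folds <- tibble::tibble(
    fold = seq_len(k),
    test_pos = pos[(seq_len(k) - 1L) %% n1 + 1L],
    test_neg = neg[(seq_len(k) - 1L) %% n0 + 1L]
  )
  reuse <- if (n1 > n0) neg[seq_len(n1 - n0)] else
    if (n0 > n1) pos[seq_len(n0 - n1)] else character(0)
  structure(
    list(folds = folds, reuse_ids = reuse,
         ids = labels$id, labels = stats::setNames(labels$label, labels$id)),
    class = "fold_plan"
  )
}

#' @export
print.fold_plan <- function(x, ...) {
  cat("<fold_plan>", nrow(x$folds), "folds,", length(x$reuse_ids),
      "reused label-0 children\n")
  invisible(x)
}
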