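# The two analysis grids of the experiment. Grid one compares the four
# classifiers on the full feature set of each game; grid two fixes the best
# classifier and sweeps every level subset of the speed game crossed with
# the three feature families. All configurations within a grid share one
# fold plan, so fold-wise scores are paired for the Wilcoxon comparisons.

#' Analysis one: classifiers x games
#'
#' Cross-validates each classifier on the full-game, all-features table of
#' both games, under a single shared fold plan.
#'
#' @param features_roadrunner,features_maze Feature tibbles for the same
#'   cohort (family `"both"`, all levels).
#' @param seed Integer seed for the fold plan and classifier randomness.
#' @param classifiers Named list of [classifier_spec()]s.
#' @param plan Optional pre-built [build_fold_plan()]; defaults to a plan
#'   from the roadrunner table's labels.
#' @return A `run_grid` tibble: `game`, `classifier`, `levels`, `family`,
#'   the three mean scores, and a `result` list-column of `run_result`s.
#'   The shared plan is attached as attribute `plan`.
#' @export
run_analysis_one <- function(features_roadrunner, features_maze, seed = 1L,
                             classifiers = default_classifiers(),
                             plan = NULL) {
  stopifnot(identical(sort(features_roadrunner$id), sort(features_maze$id)))
  plan <- plan %||% build_fold_plan(features_roadrunner, derive_seed(seed, 11))
  tables <- list(roadrunner = features_roadrunner, maze = features_maze)
  grid <- tidyr::expand_grid(game = names(tables),
                             classifier = names(classifiers))
  grid$result <- purrr::pmap(grid, function(game, classifier) {
    evaluate_config(tables[[game]], classifiers[[classifier]], plan, seed)
  })
  finish_grid(grid, plan)
}

#' Analysis two: level subsets x feature families
#'
#' For the best classifier from analysis one, cross-validates every
#' nonempty subset of the roadrunner levels crossed with the sensor, game
#' and combined feature families, all under one shared fold plan.
#'
#' @param feature_grid Output of [cohort_feature_grid()] covering the
#'   requested selectors (see [level_family_selectors()]).
#' @param spec The classifier to use, a [classifier_spec()].
#' @param seed Integer seed.
#' @param plan Optional shared [build_fold_plan()].
#' @return A `run_grid` tibble (21 rows for the full selector set).
#' @export
run_analysis_two <- function(feature_grid, spec, seed = 1L, plan = NULL) {
  plan <- plan %||% build_fold_plan(feature_grid$data[[1]],
                                    derive_seed(seed, 11))
  grid <- tibble::tibble(
    game = purrr::map_chr(feature_grid$data, ~ .x$game[1]),
    classifier = spec$kind,
    result = purrr::map(feature_grid$data, evaluate_config,
                        spec = spec, plan = plan, seed = seed)
  )
  finish_grid(grid, plan)
}

#' Selector set for analysis two
#'
#' The seven nonempty level subsets of the roadrunner game crossed with the
#' three feature families.
#'
#' @return Tibble with list-column `levels` and column `family` (21 rows).
#' @export
level_family_selectors <- function() {
  subsets <- list(0L, 1L, 2L, c(0L, 1L), c(0L, 2L), c(1L, 2L), c(0L, 1L, 2L))
  tidyr::expand_grid(levels = subsets, family = c("both", "sensor", "game"))
}

finish_grid <- function(grid, plan) {
  grid$levels <- purrr::map_chr(grid$result, ~ .x$config$levels)
  grid$family <- purrr::map_chr(grid$result, ~ .x$config$family)
  grid$accuracy <- purrr::map_dbl(grid$result, ~ .x$means[["accuracy"]])
  grid$f1 <- purrr::map_dbl(grid$result, ~ .x$means[["f1"]])
  grid$recall <- purrr::map_dbl(grid$result, ~ .x$means[["recall"]])
  grid <- grid[, c("game", "classifier", "levels", "family",
                   "accuracy", "f1", "recall", "result")]
  attr(grid, "plan") <- plan
  class(grid) <- c("run_grid", class(grid))
  grid
}

# Fold-wise scores of one grid row as a vector.
grid_scores <- function(grid, row, metric) {
  grid$result[[row]]$folds[[metric]]
}

#' Tidy a run grid into fold-wise scores
#' @param x A `run_grid`.
#' @param ... Unused.
#' @return Tibble with one row per configuration, fold and metric.
#' @exportS3Method generics::tidy
tidy.run_grid <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$result, tidy))
}

#' Per-configuration summary of a run grid
#' @param x A `run_grid`.
#' @param ... Unused.
#' @return Tibble with one row per configuration and the mean scores.
#' @exportS3Method generics::glance
glance.run_grid <- function(x, ...) {
  dplyr::bind_rows(purrr::map(x$result, glance))
}
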