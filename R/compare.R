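# The four comparison tables: paired Wilcoxon tests over fold-wise scores
# between configurations of the shared-plan analysis grids.
#
#   best-vs-classifiers:   best classifier vs the other three, per game
#   game-vs-game:          roadrunner vs maze, per classifier
#   best-vs-levels:        best level subset vs the other six (family both)
#   family-vs-family:      both/sensor/game pairings at the best subset
#
# Each row carries a two-sided p-value and its significance flag at the
# per-test alpha (no multiple-testing correction, by design).

compare_row <- function(label, metric, sa, sb, alpha, ...) {
  p <- wilcoxon_paired(sa, sb, ...)$p_value
  tibble::tibble(comparison = label, metric = metric, p_value = p,
                 significant = p < alpha)
}

pick_best <- function(grid, metric = "accuracy") {
  grid$classifier[which.max(grid[[metric]])]
}

#' Build the comparison tables from the analysis grids
#'
#' Emits the four Wilcoxon comparison tables over fold-wise accuracy and F1
#' scores. The grids must be paired: every configuration inside a grid
#' shares the same fold plan, so fold k always tests the same two children.
#'
#' @param grid_one `run_grid` from [run_analysis_one()].
#' @param grid_two Optional `run_grid` from [run_analysis_two()]; tables 3
#'   and 4 of the output need only `grid_one`.
#' @param alpha Per-test significance level.
#' @param metrics Metrics to compare.
#' @param best_classifier,best_levels Override the automatic selection
#'   (highest mean accuracy) of the reference classifier / level subset.
#' @param ... Passed to [wilcoxon_paired()] (zero policy, method).
#' @return List of class `comparison_tables` with tibbles
#'   `best_vs_classifiers`, `game_vs_game`, and, when `grid_two` is given,
#'   `best_vs_levels` and `family_vs_family`; plus `best_classifier` and
#'   `best_levels`.
#' @export
compare_tables <- function(grid_one, grid_two = NULL, alpha = 0.05,
                           metrics = c("accuracy", "f1"),
                           best_classifier = NULL, best_levels = NULL, ...) {
  check_paired(grid_one)
  best_classifier <- best_classifier %||% pick_best(grid_one)
  games <- unique(grid_one$game)
  others <- setdiff(unique(grid_one$classifier), best_classifier)

  t3 <- purrr::pmap_dfr(
    tidyr::expand_grid(cls = others, game = games, metric = metrics),
    function(cls, game, metric) {
      a <- grid_row(grid_one, game = game, classifier = best_classifier)
      b <- grid_row(grid_one, game = game, classifier = cls)
      dplyr::bind_cols(
        tibble::tibble(game = game),
        compare_row(paste(best_classifier, "vs", cls), metric,
                    grid_scores(grid_one, a, metric),
                    grid_scores(grid_one, b, metric), alpha, ...)
      )
    }
  )

  t4 <- purrr::pmap_dfr(
    tidyr::expand_grid(cls = unique(grid_one$classifier), metric = metrics),
    function(cls, metric) {
      a <- grid_row(grid_one, game = "roadrunner", classifier = cls)
      b <- grid_row(grid_one, game = "maze", classifier = cls)
      dplyr::bind_cols(
        tibble::tibble(classifier = cls),
        compare_row("roadrunner vs maze", metric,
                    grid_scores(grid_one, a, metric),
                    grid_scores(grid_one, b, metric), alpha, ...)
      )
    }
  )

  out <- list(best_vs_classifiers = t3, game_vs_game = t4,
              best_classifier = best_classifier, alpha = alpha)

  if (!is.null(grid_two)) {
    check_paired(grid_two)
    both <- grid_two[grid_two$family == "both", ]
    best_levels <- best_levels %||% both$levels[which.max(both$accuracy)]
    other_levels <- setdiff(both$levels, best_levels)

    out$best_vs_levels <- purrr::pmap_dfr(
      tidyr::expand_grid(lv = other_levels, metric = metrics),
      function(lv, metric) {
        a <- grid_row(grid_two, levels = best_levels, family = "both")
        b <- grid_row(grid_two, levels = lv, family = "both")
        dplyr::bind_cols(
          tibble::tibble(levels = lv),
          compare_row(paste("levels", best_levels, "vs", lv), metric,
                      grid_scores(grid_two, a, metric),
                      grid_scores(grid_two, b, metric), alpha, ...)
        )
      }
    )

    pairs <- list(c("both", "sensor"), c("both", "game"), c("sensor", "game"))
    out$family_vs_family <- purrr::pmap_dfr(
      tidyr::expand_grid(pair = pairs, metric = metrics),
      function(pair, metric) {
        a <- grid_row(grid_two, levels = best_levels, family = pair[1])
        b <- grid_row(grid_two, levels = best_levels, family = pair[2])
        compare_row(paste(pair[1], "vs", pair[2], "features"), metric,
                    grid_scores(grid_two, a, metric),
                    grid_scores(grid_two, b, metric), alpha, ...)
      }
    )
    out$best_levels <- best_levels
  }
  structure(out, class = "comparison_tables")
}

grid_row <- function(grid, game = NULL, classifier = NULL, levels = NULL,
                     family = NULL) {
  keep <- rep(TRUE, nrow(grid))
  if (!is.null(game)) keep <- keep & grid$game == game
  if (!is.null(classifier)) keep <- keep & grid$classifier == classifier
  if (!is.null(levels)) keep <- keep & grid$levels == levels
  if (!is.null(family)) keep <- keep & grid$family == family
  idx <- which(keep)
  if (length(idx) != 1) stop("grid selection did not identify a unique row")
  idx
}

check_paired <- function(grid) {
  if (is.null(attr(grid, "plan"))) {
    stop("grid carries no shared fold plan; comparisons require paired folds")
  }
  invisible(grid)
}

#' @export
print.comparison_tables <- function(x, ...) {
  cat("<comparison_tables> best classifier:", x$best_classifier)
  if (!is.null(x$best_levels)) cat(", best levels:", x$best_levels)
  cat("\n")
  for (nm in intersect(c("best_vs_classifiers", "game_vs_game",
                         "best_vs_levels", "family_vs_family"), names(x))) {
    cat("--", nm, "--\n")
    print(as.data.frame(x[[nm]]), digits = 3)
  }
  invisible(x)
}

#' Tidy the comparison tables into one long tibble
#' @param x A `comparison_tables` object.
#' @param ... Unused.
#' @return Tibble with a `table` column and one row per comparison.
#' @exportS3Method generics::tidy
tidy.comparison_tables <- function(x, ...) {
  nms <- intersect(c("best_vs_classifiers", "game_vs_game",
                     "best_vs_levels", "family_vs_family"), names(x))
  dplyr::bind_rows(purrr::map(
    stats::setNames(nms, nms),
    ~ dplyr::select(x[[.x]], dplyr::any_of(c("comparison", "game",
                                             "classifier", "levels",
                                             "metric", "p_value",
                                             "significant")))
  ), .id = "table")
}
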