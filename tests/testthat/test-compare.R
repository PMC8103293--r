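# run_grid built directly from synthetic fold scores: fast and lets the
# comparisons be checked against hand-computable cases
fake_grid <- function(configs, score_list, n_folds = 12) {
  plan <- structure(list(folds = tibble::tibble(fold = seq_len(n_folds)),
                         reuse_ids = character(0)),
                    class = "fold_plan")
  results <- purrr::pmap(configs, function(game, classifier, levels, family,
                                           idx) {
    sc <- score_list[[idx]]
    structure(
      list(config = list(classifier = classifier, game = game,
                         levels = levels, family = family),
           folds = tibble::tibble(fold = seq_len(n_folds), accuracy = sc,
                                  f1 = sc, recall = sc),
           means = c(accuracy = mean(sc), f1 = mean(sc), recall = mean(sc))),
      class = "run_result"
    )
  })
  grid <- tibble::tibble(game = configs$game, classifier = configs$classifier,
                         result = results)
  motorcube:::finish_grid(grid, plan)
}

grid_one_fake <- function(seed = 1, shift_dt = 0.3) {
  withr::with_seed(seed, {
    configs <- tidyr::expand_grid(
      game = c("roadrunner", "maze"),
      classifier = c("knn", "logistic_regression", "decision_tree", "svm")
    )
    configs$levels <- "0+1+2"; configs$family <- "both"
    configs$idx <- seq_len(nrow(configs))
    scores <- purrr::map(seq_len(nrow(configs)), function(i) {
      base <- stats::runif(12, 0.3, 0.8)
      if (configs$classifier[i] == "decision_tree") base + shift_dt else base
    })
    fake_grid(configs, scores)
  })
}

test_that("comparison tables have the standard grid structure", {
  g1 <- grid_one_fake()
  tabs <- compare_tables(g1)
  expect_equal(tabs$best_classifier, "decision_tree")
  # best vs other classifiers: 3 rows x 2 games x 2 metrics
  expect_equal(nrow(tabs$best_vs_classifiers), 12)
  expect_equal(nrow(dplyr::distinct(tabs$best_vs_classifiers[, "game"])), 2)
  # game vs game: 4 classifiers x 2 metrics
  expect_equal(nrow(tabs$game_vs_game), 8)
  expect_true(all(tabs$game_vs_game$comparison == "roadrunner vs maze"))
  expect_true(all(tabs$best_vs_classifiers$p_value >= 0))
  expect_true(all(tabs$best_vs_classifiers$p_value <= 1))
  expect_identical(tabs$best_vs_classifiers$significant,
                   tabs$best_vs_classifiers$p_value < 0.05)
})

test_that("a grid compared with itself is all p = 1 and never flagged", {
  g1 <- grid_one_fake(shift_dt = 0)
  # comparing each game with itself: duplicate one game's scores
  g_dup <- g1
  g_dup$result <- purrr::map(seq_len(nrow(g_dup)), function(i) {
    r <- g1$result[[motorcube:::grid_row(g1, game = "roadrunner",
                                         classifier = g1$classifier[i])]]
    r$config$game <- g_dup$game[i]
    r
  })
  g_dup <- motorcube:::finish_grid(g_dup[, c("game", "classifier", "result")],
                                   attr(g1, "plan"))
  tabs <- compare_tables(g_dup)
  expect_true(all(tabs$game_vs_game$p_value == 1))
  expect_false(any(tabs$game_vs_game$significant))
})

test_that("level and family tables cover the right comparison rows", {
  withr::with_seed(2, {
    sels <- level_family_selectors()
    configs <- tibble::tibble(
      game = "roadrunner", classifier = "decision_tree",
      levels = purrr::map_chr(sels$levels, paste, collapse = "+"),
      family = sels$family, idx = seq_len(nrow(sels))
    )
    scores <- purrr::map(configs$idx, function(i) {
      boost <- if (configs$levels[i] == "0+2" && configs$family[i] == "both")
        0.35 else 0
      stats::runif(12, 0.3, 0.6) + boost
    })
    g2 <- fake_grid(configs, scores)
  })
  tabs <- compare_tables(grid_one_fake(), g2)
  expect_equal(tabs$best_levels, "0+2")
  # 6 other level subsets x 2 metrics
  expect_equal(nrow(tabs$best_vs_levels), 12)
  # both-vs-sensor, both-vs-game, sensor-vs-game x 2 metrics
  expect_equal(nrow(tabs$family_vs_family), 6)
  expect_setequal(unique(tabs$family_vs_family$comparison),
                  c("both vs sensor features", "both vs game features",
                    "sensor vs game features"))
  td <- generics::tidy(tabs)
  expect_setequal(unique(td$table),
                  c("best_vs_classifiers", "game_vs_game", "best_vs_levels",
                    "family_vs_family"))
})

test_that("unpaired grids are rejected", {
  g1 <- grid_one_fake()
  attr(g1, "plan") <- NULL
  expect_error(compare_tables(g1), "fold plan")
})
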