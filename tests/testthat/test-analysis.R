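# small synthetic feature tables (no simulation) exercising the grid
# plumbing; labels balanced so plans are valid either way
make_tables <- function(n = 20, seed = 5) {
  withr::with_seed(seed, {
    label <- rep(c(1L, 0L), each = n / 2)
    base <- tibble::tibble(
      id = sprintf("c%02d", seq_len(n)),
      age = stats::runif(n, 6.5, 9), gender = rep(c(0, 1), n / 2),
      label = label
    )
    mk <- function(game, levels, family, signal) {
      cols <- setdiff(feature_columns(family), c("age", "gender"))
      vals <- purrr::map(cols, ~ label * signal + stats::rnorm(n))
      names(vals) <- cols
      dplyr::bind_cols(base[, "id"], tibble::as_tibble(vals),
                       base[, c("age", "gender", "label")],
                       tibble::tibble(game = game,
                                      levels = paste(levels, collapse = "+")))
    }
    list(rr = mk("roadrunner", 0:2, "both", 3),
         mz = mk("maze", 0:1, "both", 0.3), mk = mk)
  })
}

test_that("analysis one yields the 4 x 2 grid under one shared plan", {
  tabs <- make_tables()
  g <- run_analysis_one(tabs$rr, tabs$mz, seed = 1)
  expect_s3_class(g, "run_grid")
  expect_equal(nrow(g), 8)
  expect_setequal(unique(g$game), c("roadrunner", "maze"))
  expect_setequal(unique(g$classifier),
                  c("knn", "logistic_regression", "decision_tree", "svm"))
  # paired design: every configuration shares identical test pairs per fold
  plan <- attr(g, "plan")
  expect_s3_class(plan, "fold_plan")
  for (r in g$result) expect_equal(nrow(r$folds), nrow(plan$folds))
})

test_that("analysis two yields the 21-selector grid on shared folds", {
  tabs <- make_tables()
  sels <- level_family_selectors()
  expect_equal(nrow(sels), 21)
  fg <- sels
  fg$data <- purrr::pmap(sels, function(levels, family) {
    tabs$mk("roadrunner", levels, family, 2)
  })
  plan <- build_fold_plan(fg$data[[1]], seed = 9)
  g <- run_analysis_two(fg, classifier_spec("decision_tree"), seed = 2,
                        plan = plan)
  expect_equal(nrow(g), 21)
  expect_setequal(unique(g$family), c("both", "sensor", "game"))
  expect_setequal(unique(g$levels),
                  c("0", "1", "2", "0+1", "0+2", "1+2", "0+1+2"))
  expect_true(all(g$classifier == "decision_tree"))
})

test_that("the all-levels/both row of analysis two equals analysis one", {
  tabs <- make_tables()
  plan <- build_fold_plan(tabs$rr, seed = 3)
  spec <- classifier_spec("decision_tree")
  g1 <- run_analysis_one(tabs$rr, tabs$mz, seed = 4, plan = plan)
  fg <- tibble::tibble(levels = list(c(0L, 1L, 2L)), family = "both",
                       data = list(tabs$rr))
  g2 <- run_analysis_two(fg, spec, seed = 4, plan = plan)
  r1 <- g1$result[[motorcube:::grid_row(g1, game = "roadrunner",
                                        classifier = "decision_tree")]]
  expect_equal(g2$result[[1]]$folds, r1$folds)
})

test_that("general features enter every configuration's design matrix", {
  fg <- level_family_selectors()
  tabs <- make_tables()
  fg$data <- purrr::pmap(fg, function(levels, family) {
    tabs$mk("roadrunner", levels, family, 2)
  })
  for (d in fg$data) {
    expect_true(all(c("age", "gender") %in% names(d)))
  }
})

test_that("label-shuffled features score near chance for every classifier", {
  tabs <- fix_cohort_tables(1)
  accs <- sapply(1:6, function(s) {
    shuffled <- tabs$roadrunner
    shuffled$label <- withr::with_seed(s, sample(shuffled$label))
    plan <- build_fold_plan(shuffled, seed = s)
    vapply(default_classifiers(), function(spec) {
      evaluate_config(shuffled, spec, plan, seed = s)$means[["accuracy"]]
    }, numeric(1))
  })
  expect_true(all(rowMeans(accs) > 0.4 & rowMeans(accs) < 0.6))
})
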