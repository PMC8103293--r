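# The four classifiers of the experiment and the per-fold evaluation loop.
# Standard fitters are used (class::knn, glmnet ridge logistic, rpart with
# the Gini criterion, e1071 radial SVM); the bespoke part is the fold plan
# and the 2-sample-test-fold metric bookkeeping.

#' Classifier specification
#'
#' Documented defaults: KNN with k = 5; ridge-penalised logistic regression
#' with penalty 1/n_train; decision tree with the Gini criterion and
#' unlimited depth; radial-kernel SVM with unit cost. All but the tree
#' standardise features with training-fold statistics.
#'
#' @param kind One of `"knn"`, `"logistic_regression"`, `"decision_tree"`,
#'   `"svm"`.
#' @param standardize Standardise predictors with train-fold mean/sd.
#' @param k Neighbours for KNN.
#' @param cost SVM cost.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("knn", "logistic_regression",
                                     "decision_tree", "svm"),
                            standardize = NULL, k = 5L, cost = 1) {
  kind <- match.arg(kind)
  structure(
    list(kind = kind,
         standardize = standardize %||% (kind != "decision_tree"),
         k = k, cost = cost),
    class = "classifier_spec"
  )
}

#' The four default classifier specifications
#' @return Named list of `classifier_spec`s.
#' @export
default_classifiers <- function() {
  kinds <- c("knn", "logistic_regression", "decision_tree", "svm")
  stats::setNames(lapply(kinds, classifier_spec), kinds)
}

# Fit on train, predict test; both matrices already standardized if asked.
fit_predict <- function(spec, x_train, y_train, x_test) {
  y_train <- factor(y_train, levels = c(0, 1))
  pred <- switch(
    spec$kind,
    knn = as.integer(as.character(
      class::knn(x_train, x_test, y_train, k = spec$k)
    )),
    logistic_regression = {
      fit <- glmnet::glmnet(x_train, y_train, family = "binomial",
                            alpha = 0, lambda = 1 / nrow(x_train),
                            standardize = FALSE)
      as.integer(as.character(
        stats::predict(fit, x_test, type = "class")[, 1]
      ))
    },
    decision_tree = {
      df <- as.data.frame(x_train); df$.y <- y_train
      fit <- rpart::rpart(.y ~ ., df, method = "class",
                          parms = list(split = "gini"),
                          control = rpart::rpart.control(
                            minsplit = 2, minbucket = 1, cp = 0,
                            maxdepth = 30, xval = 0))
      as.integer(as.character(
        stats::predict(fit, as.data.frame(x_test), type = "class")
      ))
    },
    svm = {
      fit <- e1071::svm(x_train, y_train, kernel = "radial",
                        cost = spec$cost, scale = FALSE)
      as.integer(as.character(stats::predict(fit, x_test)))
    }
  )
  pred
}

# accuracy / recall-of-label-1 / F1 with the F1 := 0 zero-division policy
fold_metrics <- function(pred, truth) {
  tp <- sum(pred == 1 & truth == 1)
  fp <- sum(pred == 1 & truth == 0)
  fn <- sum(pred == 0 & truth == 1)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = mean(pred == truth), f1 = f1, recall = recall)
}

#' Cross-validate one classifier on one feature table
#'
#' Runs the fold plan: per fold, fit on all children outside the test pair
#' (standardising with training-fold statistics where the spec says so),
#' predict the two test children, and record accuracy, recall of label 1,
#' and F1 (defined as 0 when precision and recall are both 0, which
#' 2-sample test folds make possible).
#'
#' @param features Feature tibble: `id`, predictor columns, `label` (plus
#'   optional `game`/`levels` metadata).
#' @param spec A [classifier_spec()].
#' @param plan A [build_fold_plan()] plan whose ids all appear in
#'   `features`.
#' @param seed Integer seed for any classifier-level randomness (KNN tie
#'   breaks).
#' @return A `run_result`: list with `config`, `folds` (tibble `fold`,
#'   `accuracy`, `f1`, `recall`) and `means`.
#' @export
evaluate_config <- function(features, spec, plan, seed = 1L) {
  features <- tibble::as_tibble(features)
  missing <- setdiff(plan$ids, features$id)
  if (length(missing) > 0) {
    stop("feature table is missing planned ids: ",
         paste(utils::head(missing, 3), collapse = ", "))
  }
  predictors <- setdiff(names(features), c("id", "label", "game", "levels"))
  x <- as.matrix(features[, predictors])
  if (!is.numeric(x)) stop("predictor columns must be numeric")
  rownames(x) <- features$id
  y <- stats::setNames(features$label, features$id)

  n_folds <- nrow(plan$folds)
  out <- matrix(NA_real_, n_folds, 3,
                dimnames = list(NULL, c("accuracy", "f1", "recall")))
  for (i in seq_len(n_folds)) {
    test_ids <- c(plan$folds$test_pos[i], plan$folds$test_neg[i])
    train_ids <- setdiff(plan$ids, test_ids)
    xtr <- x[train_ids, , drop = FALSE]
    xte <- x[test_ids, , drop = FALSE]
    if (spec$standardize) {
      mu <- colMeans(xtr)
      sg <- apply(xtr, 2, stats::sd)
      sg[sg == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, mu), 2, sg, "/")
      xte <- sweep(sweep(xte, 2, mu), 2, sg, "/")
    }
    pred <- withr::with_seed(
      derive_seed(seed, i),
      fit_predict(spec, xtr, y[train_ids], xte)
    )
    out[i, ] <- fold_metrics(pred, y[test_ids])
  }
  structure(
    list(
      config = list(classifier = spec$kind,
                    game = features$game[1] %||% NA_character_,
                    levels = features$levels[1] %||% NA_character_,
                    family = feature_family(predictors)),
      folds = dplyr::bind_cols(tibble::tibble(fold = seq_len(n_folds)),
                               tibble::as_tibble(out)),
      means = colMeans(out)
    ),
    class = "run_result"
  )
}

feature_family <- function(predictors) {
  has_sensor <- any(SENSOR_FEATURES %in% predictors)
  has_game <- any(GAME_FEATURES %in% predictors)
  if (has_sensor && has_game) "both" else if (has_sensor) "sensor" else "game"
}

#' @export
print.run_result <- function(x, ...) {
  cat("<run_result>", x$config$classifier, "on", x$config$game,
      "levels", x$config$levels, "family", x$config$family, "\n  means:",
      paste(names(x$means), round(x$means, 3), collapse = ", "), "\n")
  invisible(x)
}

#' @importFrom generics tidy glance
NULL

#' Tidy a cross-validation result into fold-wise scores
#' @param x A `run_result`.
#' @param ... Unused.
#' @return Tibble with config columns and one row per fold and metric.
#' @exportS3Method generics::tidy
tidy.run_result <- function(x, ...) {
  tidyr::pivot_longer(
    dplyr::bind_cols(tibble::as_tibble(x$config), x$folds),
    c("accuracy", "f1", "recall"),
    names_to = "metric", values_to = "score"
  )
}

#' One-row summary of a cross-validation result
#' @param x A `run_result`.
#' @param ... Unused.
#' @return One-row tibble with config columns and the three mean scores.
#' @exportS3Method generics::glance
glance.run_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$config),
    tibble::tibble(accuracy = x$means[["accuracy"]], f1 = x$means[["f1"]],
                   recall = x$means[["recall"]], n_folds = nrow(x$folds))
  )
}
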