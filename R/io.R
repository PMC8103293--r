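# Plain-text interchange formats: sensor streams and tables as CSV (9
# significant digits — below sensor noise, above float32 round-off), event
# logs as JSON Lines with a header record, result grids as JSON.

CSV_DIGITS <- 9L

fmt_num <- function(x) {
  ifelse(is.na(x), NA_character_, formatC(signif(x, CSV_DIGITS),
                                          digits = CSV_DIGITS, format = "g"))
}

#' Write / read a sensor stream CSV
#'
#' Columns `t, ax, ay, az, gx, gy, gz` in SI units, 9 significant digits.
#'
#' @param stream Sensor stream tibble.
#' @param path File path.
#' @return `read_sensor_csv` returns the stream tibble; the writer returns
#'   `path` invisibly.
#' @export
write_sensor_csv <- function(stream, path) {
  out <- dplyr::mutate(stream, dplyr::across(dplyr::everything(), fmt_num))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_sensor_csv
#' @export
read_sensor_csv <- function(path) {
  if (!file.exists(path)) stop("sensor file not found: ", path)
  readr::read_csv(path, col_types = readr::cols(.default = readr::col_double()))
}

#' Write / read a session log as JSON Lines
#'
#' First record is a header (`child_id`, `game`, `permutation`, `seed`);
#' each following line is one event `{"t": ..., "kind": ..., "cell": ...,
#' "lod": ...}`. On read, the schedule is rebuilt from the game and
#' permutation id and warm-up flags from the 60 s warm-up window.
#'
#' @param log A `session_log`.
#' @param path File path.
#' @return `read_session_jsonl` returns a `session_log`; the writer returns
#'   `path` invisibly.
#' @export
write_session_jsonl <- function(log, path) {
  header <- jsonlite::toJSON(
    list(child_id = log$child_id, game = log$game,
         permutation = log$permutation, seed = log$seed),
    auto_unbox = TRUE, null = "null", na = "null"
  )
  ev <- purrr::pmap_chr(
    log$events[, c("t", "kind", "cell", "lod")],
    function(t, kind, cell, lod) {
      jsonlite::toJSON(list(t = t, kind = kind, cell = cell, lod = lod),
                       auto_unbox = TRUE, na = "null", digits = NA)
    }
  )
  writeLines(c(header, ev), path)
  invisible(path)
}

#' @rdname write_session_jsonl
#' @export
read_session_jsonl <- function(path) {
  if (!file.exists(path)) stop("session log not found: ", path)
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  recs <- purrr::map(lines[-1], jsonlite::fromJSON)
  events <- tibble::tibble(
    t = purrr::map_dbl(recs, "t"),
    kind = purrr::map_chr(recs, "kind"),
    cell = purrr::map_int(recs, ~ if (is.null(.x$cell)) NA_integer_ else
      as.integer(.x$cell)),
    lod = purrr::map_int(recs, ~ if (is.null(.x$lod)) NA_integer_ else
      as.integer(.x$lod))
  )
  schedule <- if (header$game == "roadrunner") {
    roadrunner_schedule(header$permutation %||% 0L)
  } else {
    maze_schedule()
  }
  events$warmup <- events$t < schedule$warmup_duration &
    events$kind != "session_end"
  new_session_log(header$child_id, header$game, schedule, events,
                  header$seed %||% NA_integer_)
}

#' Write / read a cohort manifest CSV
#'
#' Columns `id, age, gender, percentile, label`. The latent skill is
#' deliberately not part of the manifest (it is unobservable in a real
#' cohort).
#'
#' @param cohort Cohort tibble from [sample_cohort()].
#' @param path File path.
#' @return `read_manifest_csv` returns the manifest tibble; the writer
#'   returns `path` invisibly.
#' @export
write_manifest_csv <- function(cohort, path) {
  out <- dplyr::mutate(cohort[, c("id", "age", "gender", "percentile", "label")],
                       age = fmt_num(age))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), age = readr::col_double(),
    gender = readr::col_character(), percentile = readr::col_integer(),
    label = readr::col_integer()
  ))
}

#' Write / read a feature table CSV
#'
#' @param features Feature tibble from [cohort_features()].
#' @param path File path.
#' @return `read_feature_csv` returns the feature tibble; the writer
#'   returns `path` invisibly.
#' @export
write_feature_csv <- function(features, path) {
  num <- names(features)[vapply(features, is.double, logical(1))]
  out <- dplyr::mutate(features, dplyr::across(dplyr::all_of(num), fmt_num))
  readr::write_csv(out, path)
  invisible(path)
}

#' @rdname write_feature_csv
#' @export
read_feature_csv <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  readr::read_csv(path, col_types = readr::cols(
    id = readr::col_character(), game = readr::col_character(),
    levels = readr::col_character(), label = readr::col_integer(),
    gender = readr::col_double(), .default = readr::col_double()
  ))
}

#' Write / read a run grid as JSON
#'
#' Serialises every configuration with its fold-wise score vectors and
#' means, so comparisons can be recomputed from the file.
#'
#' @param grid A `run_grid`.
#' @param path File path.
#' @return `read_run_grid_json` returns a `run_grid` (without the original
#'   fold plan object; pairing is preserved through the stored plan digest);
#'   the writer returns `path` invisibly.
#' @export
write_run_grid_json <- function(grid, path) {
  payload <- list(
    plan = list(
      folds = attr(grid, "plan")$folds,
      reuse_ids = attr(grid, "plan")$reuse_ids
    ),
    configs = purrr::map(grid$result, function(r) {
      list(config = r$config,
           folds = as.list(r$folds[, c("accuracy", "f1", "recall")]),
           means = as.list(r$means))
    })
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_grid_json
#' @export
read_run_grid_json <- function(path) {
  if (!file.exists(path)) stop("results file not found: ", path)
  payload <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  results <- purrr::map(payload$configs, function(cfg) {
    folds <- tibble::tibble(
      fold = seq_along(cfg$folds$accuracy),
      accuracy = unlist(cfg$folds$accuracy),
      f1 = unlist(cfg$folds$f1),
      recall = unlist(cfg$folds$recall)
    )
    structure(
      list(config = cfg$config, folds = folds,
           means = unlist(cfg$means)),
      class = "run_result"
    )
  })
  grid <- tibble::tibble(
    game = purrr::map_chr(results, ~ .x$config$game %||% NA_character_),
    classifier = purrr::map_chr(results, ~ .x$config$classifier),
    result = results
  )
  plan_folds <- dplyr::bind_rows(purrr::map(payload$plan$folds, tibble::as_tibble))
  plan <- structure(
    list(folds = plan_folds,
         reuse_ids = unlist(payload$plan$reuse_ids) %||% character(0),
         ids = NULL, labels = NULL),
    class = "fold_plan"
  )
  finish_grid(grid, plan)
}

#' Write the comparison tables to CSV files
#'
#' One CSV per table, named `comparison_<table>.csv`, in `dir`; plus a
#' combined JSON report `comparisons.json`.
#'
#' @param tables A `comparison_tables` object.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_comparison_csv <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nms <- intersect(c("best_vs_classifiers", "game_vs_game",
                     "best_vs_levels", "family_vs_family"), names(tables))
  for (nm in nms) {
    readr::write_csv(tables[[nm]], file.path(dir, paste0("comparison_", nm, ".csv")))
  }
  jsonlite::write_json(
    list(best_classifier = tables$best_classifier,
         best_levels = tables$best_levels,
         alpha = tables$alpha,
         tables = purrr::map(tables[nms], ~ as.data.frame(.x))),
    file.path(dir, "comparisons.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
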