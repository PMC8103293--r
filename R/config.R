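# Run configuration: every constant of the protocol in one place, with
# defaults matching the study conditions, overridable from a flat YAML
# key-value file.

#' Default run configuration
#'
#' The defaults reproduce the protocol constants: 110 Hz sampling, dot
#' delays 0.8/0.6/0.4 s for levels 0/1/2, 30 s roadrunner and 60 s maze
#' segments, a 60 s warm-up, a 4 Hz 4th-order zero-phase low-pass,
#' percentile cut-off 16 for label 1, and alpha = 0.05 for all tests.
#'
#' @return Named list of configuration values.
#' @export
default_config <- function() {
  list(
    sample_rate = 110,
    delays = c(0.8, 0.6, 0.4),
    roadrunner_segment_s = 30,
    maze_segment_s = 60,
    warmup_s = 60,
    filter_cutoff_hz = 4,
    filter_order = 4,
    percentile_cutoff = 16,
    alpha = 0.05,
    cohort_n = 95,
    prevalence = 49 / 95,
    knn_k = 5,
    svm_cost = 1,
    seed = 1
  )
}

#' Read a run configuration file
#'
#' Flat YAML key-value file; keys present in the file override the
#' defaults, unknown keys raise an error.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(cfg, user)
}
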