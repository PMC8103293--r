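# Feature extraction: one session (sensor stream + event log) becomes one
# row of the feature table. Streams are filtered per axis at 4 Hz
# (zero-phase), magnitudes and their derivatives form the sensor signals,
# the game channel is the dot-alignment cosine (roadrunner) or the on-path
# indicator (maze); the warm-up minute is dropped, the selected levels are
# pooled (both occurrences of each level), and each signal contributes its
# mean and standard deviation.

SENSOR_FEATURES <- c("a_mean", "a_sd", "w_mean", "w_sd",
                     "jerk_mean", "jerk_sd", "alpha_mean", "alpha_sd")
GAME_FEATURES <- c("game_mean", "game_sd")
GENERAL_FEATURES <- c("age", "gender")

#' Predictor column names for a feature family
#'
#' @param family `"sensor"`, `"game"` or `"both"`. The two general features
#'   (age, gender) are always included.
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(family = c("both", "sensor", "game")) {
  family <- match.arg(family)
  c(switch(family,
           sensor = SENSOR_FEATURES,
           game = GAME_FEATURES,
           both = c(SENSOR_FEATURES, GAME_FEATURES)),
    GENERAL_FEATURES)
}

#' Per-sample dot-alignment cosine similarity
#'
#' Reconstructs, from the recorded channels alone, how well the player kept
#' the dot's face up: the cosine between the current dot cell's direction
#' and the up direction estimated as the negated, normalised low-pass
#' filtered accelerometer signal (drift-free, unlike integrating the
#' gyroscope). The dot cell is held piecewise constant between `dot_move`
#' events.
#'
#' @param stream Sensor stream tibble (`t, ax, ay, az, gx, gy, gz`).
#' @param log The paired roadrunner `session_log`.
#' @param topo A `cube_topology`.
#' @param rate Sampling rate in Hz.
#' @return Numeric vector in `[-1, 1]`, one value per stream sample.
#' @export
alignment_signal <- function(stream, log, topo = cube_topology(),
                             rate = IMU_RATE) {
  if (log$game != "roadrunner") stop("alignment is a roadrunner feature")
  acc <- lowpass(cbind(stream$ax, stream$ay, stream$az), rate)
  nrm <- sqrt(rowSums(acc^2))
  if (any(nrm == 0)) stop("cannot estimate the up direction from zero acceleration")
  up_body <- -acc / nrm
  cells <- dot_cell_at(log, stream$t)
  pmin(1, pmax(-1, rowSums(topo$centers[cells + 1L, , drop = FALSE] * up_body)))
}

#' Per-sample on-path indicator for a maze session
#'
#' Reconstructs the dot's on/off-path state at each query time from the
#' alternating `off_path_enter` / `off_path_exit` events; its mean is the
#' maze correctness (fraction of time spent on the allowed track).
#'
#' @param log A maze `session_log`.
#' @param times Query times in seconds.
#' @return Integer vector of 0/1 indicators, one per query time.
#' @export
maze_ok_signal <- function(log, times) {
  if (log$game != "maze") stop("maze correctness is a maze feature")
  ev <- log$events[log$events$kind %in% c("off_path_enter", "off_path_exit"), ]
  if (nrow(ev) > 0) {
    expected <- rep(c("off_path_enter", "off_path_exit"), length.out = nrow(ev))
    if (!all(ev$kind == expected)) {
      stop("off-path events do not alternate starting with off_path_enter")
    }
  }
  idx <- findInterval(times, ev$t)
  as.integer(idx %% 2L == 0L)
}

# Derived per-sample signals for one session: a, w, jerk, alpha and the
# game channel, all on the 110 Hz grid, computed over the full stream
# (filtering sees the whole session; windowing happens at aggregation).
session_signals <- function(session, topo = cube_topology(), rate = IMU_RATE) {
  stream <- session$stream
  acc <- lowpass(cbind(stream$ax, stream$ay, stream$az), rate)
  gyr <- lowpass(cbind(stream$gx, stream$gy, stream$gz), rate)
  a <- magnitude(acc)
  w <- magnitude(gyr)
  out <- tibble::tibble(
    t = stream$t, a = a, w = w,
    jerk = differentiate(a, rate), alpha = differentiate(w, rate)
  )
  if (session$log$game == "roadrunner") {
    out$game_signal <- alignment_signal(stream, session$log, topo, rate)
  } else {
    out$game_signal <- as.numeric(maze_ok_signal(session$log, stream$t))
  }
  out
}

#' Extract the feature vector of one session
#'
#' Drops the warm-up minute, pools the samples of every scheduled segment
#' whose level is in `levels` (both occurrences of each level), and reduces
#' each derived signal to its mean and standard deviation over that pooled
#' window. Sensor features: mean/SD of total acceleration `a`, total
#' angular velocity `w`, jerk, and angular jerk `alpha` (8 values). Game
#' features: mean/SD of the cosine alignment (roadrunner) or on-path
#' indicator (maze). General features: age in years and gender
#' (girl = 0, boy = 1).
#'
#' @param session A `game_session` from [simulate_session()], or a list with
#'   elements `stream`, `log` and `child`.
#' @param levels Integer set of levels to pool (subset of the game's levels).
#' @param family Which feature family the table keeps; see
#'   [feature_columns()].
#' @param topo A `cube_topology`.
#' @return One-row tibble: `id`, the selected feature columns, `label`,
#'   `game`, `levels` (e.g. `"0+2"`).
#' @export
extract_features <- function(session, levels = NULL,
                             family = c("both", "sensor", "game"),
                             topo = cube_topology()) {
  family <- match.arg(family)
  sig <- session_signals(session, topo)
  aggregate_features(sig, session$log$schedule, session$child, levels, family)
}

# Aggregation step, separated so that one set of derived signals can serve
# several level/family selections.
aggregate_features <- function(sig, schedule, child, levels, family) {
  win <- schedule_windows(schedule)
  game_levels <- sort(unique(win$lod[!win$warmup]))
  if (is.null(levels)) levels <- game_levels
  if (!all(levels %in% game_levels)) {
    stop("`levels` must be a subset of the game's levels {",
         paste(game_levels, collapse = ","), "}")
  }
  win <- win[!win$warmup & win$lod %in% levels, , drop = FALSE]
  mask <- rep(FALSE, nrow(sig))
  for (i in seq_len(nrow(win))) {
    mask <- mask | (sig$t >= win$t0[i] & sig$t < win$t1[i])
  }
  if (!any(mask)) stop("empty aggregation window after level selection")
  sel <- sig[mask, ]
  feats <- tibble::tibble(
    a_mean = mean(sel$a), a_sd = stats::sd(sel$a),
    w_mean = mean(sel$w), w_sd = stats::sd(sel$w),
    jerk_mean = mean(sel$jerk), jerk_sd = stats::sd(sel$jerk),
    alpha_mean = mean(sel$alpha), alpha_sd = stats::sd(sel$alpha),
    game_mean = mean(sel$game_signal), game_sd = stats::sd(sel$game_signal),
    age = child$age, gender = as.integer(child$gender == "boy")
  )
  dplyr::bind_cols(
    tibble::tibble(id = child$id),
    feats[feature_columns(family)],
    tibble::tibble(label = as.integer(child$label),
                   game = schedule$game,
                   levels = paste(sort(levels), collapse = "+"))
  )
}

#' Simulate a cohort's sessions and extract a grid of feature tables
#'
#' For each child, simulates one session of `game` and extracts features for
#' every requested (levels, family) selection from that single session, so
#' all selections describe the same play. This is the workhorse behind both
#' analysis grids.
#'
#' @param cohort Tibble from [sample_cohort()].
#' @param game `"roadrunner"` or `"maze"`.
#' @param selectors Tibble with list-column `levels` and column `family`;
#'   default is the full-game, all-features selection.
#' @param seed Integer seed; child `i` plays with sub-seed `seed + i`
#'   derivations, so cohorts are reproducible child by child.
#' @return Tibble of feature tables: `levels`, `family`, `data` (list of
#'   per-child feature tibbles bound row-wise).
#' @export
cohort_feature_grid <- function(cohort, game, selectors = NULL, seed = 1L) {
  if (is.null(selectors)) {
    selectors <- tibble::tibble(levels = list(NULL), family = "both")
  }
  rows <- vector("list", nrow(cohort))
  topo <- cube_topology()
  for (i in seq_len(nrow(cohort))) {
    child <- cohort[i, ]
    ses <- simulate_session(child, game, seed = derive_seed(seed, 100 + i))
    sig <- session_signals(ses, topo)
    rows[[i]] <- purrr::pmap(selectors, function(levels, family) {
      aggregate_features(sig, ses$log$schedule, child, levels, family)
    })
  }
  selectors$data <- purrr::map(seq_len(nrow(selectors)), function(j) {
    dplyr::bind_rows(purrr::map(rows, j))
  })
  selectors
}

#' Feature table for one cohort, one game, one selection
#'
#' Convenience wrapper around [cohort_feature_grid()] for a single
#' (levels, family) selection.
#'
#' @inheritParams cohort_feature_grid
#' @param levels Levels to pool (default: all of the game's levels).
#' @param family Feature family.
#' @return A feature tibble, one row per child.
#' @export
cohort_features <- function(cohort, game, levels = NULL, family = "both",
                            seed = 1L) {
  grid <- cohort_feature_grid(
    cohort, game,
    tibble::tibble(levels = list(levels), family = family), seed
  )
  grid$data[[1]]
}
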