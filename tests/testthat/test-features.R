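test_that("alignment recomputed from sensors matches simulator ground truth", {
  ses <- fix_rr_clean()  # noise-free session
  rec <- alignment_signal(ses$stream, ses$log)
  expect_lt(max(abs(rec - ses$truth$align)), 0.01)
  expect_gt(mean(rec), 0.8)  # skilled play keeps the dot near the top
})

test_that("a static cube scores ~0 alignment while the dot sits sideways", {
  # synthetic stream: cube at identity pose (gravity on -z), dot parked on
  # the +x face's middle cell (cell 13) for the whole session
  n <- 1100L
  stream <- tibble::tibble(
    t = (seq_len(n) - 1) / 110,
    ax = 0, ay = 0, az = -9.81, gx = 0, gy = 0, gz = 0
  )
  sch <- roadrunner_schedule(0)
  events <- tibble::tibble(
    t = c(0, 0), kind = c("level_start", "dot_move"),
    cell = c(NA_integer_, 13L), lod = c(0L, 0L), warmup = c(TRUE, TRUE)
  )
  log <- motorcube:::new_session_log("static", "roadrunner", sch, events, 1L)
  cs <- alignment_signal(stream, log)
  expect_equal(cs, rep(0, n), tolerance = 1e-9)
})

test_that("maze correctness reconstructs on/off-path time exactly", {
  sch <- maze_schedule()
  # constructed log: off path for exactly half of each playing level
  enters <- c(90, 150, 210, 270)
  exits <- enters + 30
  events <- tibble::tibble(
    t = c(0, sort(c(enters, exits))),
    kind = c("dot_move", rep(c("off_path_enter", "off_path_exit"), 4)),
    cell = 4L, lod = 0L, warmup = FALSE
  )
  log <- motorcube:::new_session_log("half", "maze", sch, events, 1L)
  t_play <- seq(60, 300 - 1e-6, by = 1 / 110)
  expect_equal(mean(maze_ok_signal(log, t_play)), 0.5, tolerance = 1e-3)
  # no off-path events at all: constant 1
  log$events <- events[1, ]
  expect_equal(mean(maze_ok_signal(log, t_play)), 1)
  # broken alternation is rejected
  log$events <- tibble::tibble(t = c(0, 90, 91), kind = c("dot_move",
                                                          "off_path_exit",
                                                          "off_path_enter"),
                               cell = 4L, lod = 0L, warmup = FALSE)
  expect_error(maze_ok_signal(log, t_play), "alternate")
})

test_that("higher maze error rates lower the correctness score", {
  frac_on <- function(err) {
    mean(vapply(1:20, function(seed) {
      log <- run_maze(maze_schedule(), maze_controller(err), seed = seed)
      mean(maze_ok_signal(log, seq(60, 299.9, by = 0.1)))
    }, numeric(1)))
  }
  expect_lt(frac_on(0.3), frac_on(0.05))
})

test_that("feature tables carry 8 sensor + 2 game + 2 general columns", {
  for (ses in list(fix_rr_session(), fix_maze_session())) {
    f <- extract_features(ses, family = "both")
    feat_cols <- setdiff(names(f), c("id", "label", "game", "levels"))
    expect_setequal(feat_cols, feature_columns("both"))
    expect_length(feat_cols, 12)  # 8 sensor + 2 game + 2 general
    expect_length(feature_columns("sensor"), 10)
    expect_length(feature_columns("game"), 4)
    expect_true(all(is.finite(as.matrix(f[feat_cols]))))
  }
})

test_that("level selection pools exactly the scheduled segments", {
  ses <- fix_rr_session()
  sig <- motorcube:::session_signals(ses)
  win <- motorcube:::schedule_windows(ses$log$schedule)
  for (lv in list(0L, 1L, 2L)) {
    sel <- win[!win$warmup & win$lod %in% lv, ]
    n_expected <- sum(vapply(seq_len(nrow(sel)), function(i) {
      sum(sig$t >= sel$t0[i] & sig$t < sel$t1[i])
    }, numeric(1)))
    expect_equal(n_expected, 60 * 110)  # two 30 s occurrences at 110 Hz
  }
  # partition: per-level masks are disjoint and union to the full selection
  masks <- lapply(0:2, function(lv) {
    sel <- win[!win$warmup & win$lod == lv, ]
    Reduce(`|`, lapply(seq_len(nrow(sel)),
                       function(i) sig$t >= sel$t0[i] & sig$t < sel$t1[i]))
  })
  expect_equal(sum(masks[[1]] & masks[[2]]), 0)
  expect_equal(sum(masks[[1]] & masks[[3]]), 0)
  expect_equal(sum(masks[[2]] & masks[[3]]), 0)
  all_mask <- sig$t >= 60
  expect_equal(masks[[1]] | masks[[2]] | masks[[3]], all_mask)
})

test_that("warm-up samples never contribute to features", {
  ses <- fix_rr_session()
  sig <- motorcube:::session_signals(ses)
  # poison the warm-up: if it leaked into aggregation the means would move
  sig2 <- sig
  sig2[sig2$t < 60, c("a", "w", "jerk", "alpha", "game_signal")] <- 1e6
  f1 <- motorcube:::aggregate_features(sig, ses$log$schedule, ses$child,
                                       NULL, "both")
  f2 <- motorcube:::aggregate_features(sig2, ses$log$schedule, ses$child,
                                       NULL, "both")
  expect_equal(f1, f2)
})

test_that("degenerate selections are rejected", {
  ses <- fix_rr_session()
  expect_error(extract_features(ses, levels = 5L), "subset")
})

test_that("constant signal inside the window yields zero SD features", {
  ses <- fix_rr_session()
  sig <- motorcube:::session_signals(ses)
  sig$a <- 9.81
  f <- motorcube:::aggregate_features(sig, ses$log$schedule, ses$child,
                                      NULL, "both")
  expect_equal(f$a_sd, 0)
  expect_equal(f$a_mean, 9.81)
})

test_that("cohort feature grids share sessions across selectors", {
  co <- sample_cohort(4, 0.5, seed = 31)
  selectors <- tibble::tibble(levels = list(c(0L, 1L, 2L), 0L),
                              family = c("both", "sensor"))
  grid <- cohort_feature_grid(co, "roadrunner", selectors, seed = 31)
  expect_equal(nrow(grid), 2)
  expect_equal(nrow(grid$data[[1]]), 4)
  # same sessions: the general features agree row by row
  expect_equal(grid$data[[1]][, c("id", "age", "gender", "label")],
               grid$data[[2]][, c("id", "age", "gender", "label")])
  expect_setequal(setdiff(names(grid$data[[2]]),
                          c("id", "label", "game", "levels")),
                  feature_columns("sensor"))
  expect_equal(grid$data[[2]]$levels[1], "0")
})
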