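test_that("cohort sampling respects size, determinism and the label rule", {
  expect_equal(nrow(sample_cohort(0, 0.5, seed = 1)), 0)
  a <- sample_cohort(25, 0.4, seed = 5)
  b <- sample_cohort(25, 0.4, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, sample_cohort(25, 0.4, seed = 6)))
  expect_true(all((a$percentile <= 16) == (a$label == 1)))
  expect_true(all(a$skill >= 0 & a$skill <= 1))
  expect_true(all(a$age >= 6.5 & a$age < 9))
  expect_error(sample_cohort(5, 1.2), "prevalence")
})

test_that("label prevalence concentrates at large n", {
  co <- sample_cohort(10000, 0.5, seed = 2)
  expect_lt(abs(mean(co$label) - 0.5), 0.02)
})

test_that("percentile is a nondecreasing function of skill", {
  s <- seq(0, 1, by = 0.01)
  p <- motorcube:::skill_to_percentile(s)
  expect_true(all(diff(p) >= 0))
  expect_equal(motorcube:::skill_to_percentile(0), 0L)
  expect_equal(motorcube:::skill_to_percentile(1), 100L)
  # the latent cutoff maps exactly onto the percentile threshold
  cut <- motorcube:::skill_cutoff()
  expect_lte(motorcube:::skill_to_percentile(cut - 1e-9), 16L)
  expect_gt(motorcube:::skill_to_percentile(cut + 1e-9), 16L)
})

test_that("control model parameters are monotone in skill", {
  lo <- control_model(0.1); hi <- control_model(0.9)
  expect_gt(hi$gain, lo$gain)
  expect_lt(hi$latency, lo$latency)
  expect_lt(hi$wobble_sd, lo$wobble_sd)
  expect_lt(hi$jitter_sd, lo$jitter_sd)
  expect_lt(hi$maze_error_rate, lo$maze_error_rate)
  mlo <- maze_control_model(0.1); mhi <- maze_control_model(0.9)
  expect_lt(mhi$wobble_sd, mlo$wobble_sd)
  expect_lt(mhi$maze_error_rate, mlo$maze_error_rate)
  expect_equal(control_model(1)$maze_error_rate, 0)
})

test_that("streams have the right length, rate and sensor ranges", {
  ses <- fix_rr_session()
  expect_equal(nrow(ses$stream), round(240 * 110))
  expect_equal(diff(ses$stream$t[1:2]), 1 / 110)
  mz <- fix_maze_session()
  expect_equal(nrow(mz$stream), round(300 * 110))
  for (s in list(ses, mz)) {
    acc <- as.matrix(s$stream[, c("ax", "ay", "az")])
    gyr <- as.matrix(s$stream[, c("gx", "gy", "gz")])
    expect_true(all(abs(acc) <= 8 * 9.81 + 1e-9))
    expect_true(all(abs(gyr) <= 2000 * pi / 180 + 1e-9))
  }
  # low-skill child, several seeds: ranges still hold
  for (seed in 1:3) {
    s <- simulate_session(fix_child(0.02, id = "weak"), "roadrunner",
                          seed = seed)
    expect_true(all(abs(s$stream[, 2:4]) <= 8 * 9.81 + 1e-9))
    expect_true(all(abs(s$stream[, 5:7]) <= 2000 * pi / 180 + 1e-9))
  }
})

test_that("sessions are reproducible from their seed", {
  a <- simulate_session(fix_child(0.4), "roadrunner",
                        schedule = roadrunner_schedule(3), seed = 17)
  b <- simulate_session(fix_child(0.4), "roadrunner",
                        schedule = roadrunner_schedule(3), seed = 17)
  expect_identical(a$stream, b$stream)
  expect_identical(a$log$events, b$log$events)
})

test_that("a perfectly skilled noise-free child never leaves the maze track", {
  ses <- simulate_session(fix_child(1), "maze", seed = 9, noise = FALSE)
  expect_equal(sum(ses$log$events$kind == "off_path_enter"), 0)
})

test_that("mean alignment increases with skill (20-seed Monte Carlo)", {
  mean_align <- function(skill) {
    mean(vapply(1:20, function(seed) {
      s <- simulate_session(fix_child(skill), "roadrunner",
                            schedule = roadrunner_schedule(seed %% 10L),
                            seed = seed)
      mean(s$truth$align[s$truth$t >= 60])
    }, numeric(1)))
  }
  expect_gt(mean_align(0.9), mean_align(0.1))
})

test_that("with noise off, integrated gyro magnitude equals the net rotation", {
  # steer the body x axis toward world up from identity: the error axis is
  # fixed, so the gyro arc length must equal the geodesic rotation angle
  n <- 1100L
  zeros <- matrix(0, n, 3)
  ones <- function(v) matrix(rep(v, each = n), n, 3)
  res <- motorcube:::.integrate_controller(
    ones(c(1, 0, 0)), ones(c(0, 0, 1)), ones(c(1, 0, 0)),
    zeros, zeros, zeros, gain = 4, dt = 1 / 110, g = 9.81, R0 = diag(3)
  )
  arc <- sum(sqrt(rowSums(res$gyro^2))) / 110
  net <- motorcube:::rotation_angle(res$rotation)
  expect_gt(net, 1)  # a substantial turn actually happened
  expect_equal(arc, net, tolerance = 1e-3)
  # and the alignment channel converged to the target
  expect_gt(res$align[n], 0.99)
})

test_that("label-1 children align worse than label-0 children (rank test)", {
  co <- sample_cohort(200, 0.5, seed = 21)
  am <- vapply(seq_len(nrow(co)), function(i) {
    s <- simulate_session(co[i, ], "roadrunner", seed = 1000 + i)
    mean(s$truth$align[s$truth$t >= 60])
  }, numeric(1))
  w <- stats::wilcox.test(am[co$label == 1], am[co$label == 0],
                          alternative = "less")
  expect_lt(w$p.value, 1e-6)
})
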