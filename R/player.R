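# Synthetic child-player generator: a latent motor-skill parameter drives a
# virtual child whose hands are an orientation feedback controller. The
# generator emits exactly what the real study recorded per session — a
# 110 Hz tri-axial accelerometer + gyroscope stream and a game event log.

IMU_RATE <- 110          # Hz
ACCEL_LIMIT <- 8 * 9.81  # +/- 8 G sensitivity, m/s^2
GYRO_LIMIT <- 2000 * pi / 180  # 2000 dps sensitivity, rad/s
GRAVITY <- 9.81

# Latent skill in [0,1] maps to an age-normed percentile; 16 or below flags
# likely fine-motor development problems (label 1).
PERCENTILE_CUTOFF <- 16L
skill_to_percentile <- function(skill) {
  pmin(100L, pmax(0L, as.integer(round(100 * skill^1.5))))
}

# skill value at which round(100 * skill^1.5) first exceeds the cutoff
skill_cutoff <- function() ((PERCENTILE_CUTOFF + 0.5) / 100)^(2 / 3)

#' Default synthetic-cohort configuration
#'
#' The latent skill is drawn from a two-component mixture: a low-skill
#' component for children flagged by the motor test and a typical-skill
#' component for the rest. Values are on the latent `[0,1]` skill scale.
#'
#' @return Named list with `low_mean`, `low_sd`, `typical_mean`,
#'   `typical_sd`, `age_range` (years) and `girl_prob`.
#' @export
cohort_config <- function() {
  list(low_mean = 0.18, low_sd = 0.10, typical_mean = 0.62, typical_sd = 0.15,
       game_skill_sd = 0.15, age_range = c(6.5, 9.0), girl_prob = 0.5)
}

#' Sample a synthetic cohort of child players
#'
#' Each child gets a binary outcome label (1 with probability `prevalence`),
#' then a latent skill drawn from the matching mixture component truncated
#' to the label's percentile region, so the percentile is a nondecreasing
#' function of skill and `label = 1` exactly when `percentile <= 16`.
#'
#' A child's in-game control ability (`game_skill`) is the latent skill
#' plus an independent trait deviation (`game_skill_sd`), clipped to
#' `[0, 1]`: the motor test and the games measure correlated but distinct
#' abilities, which is what bounds classification accuracy away from 1.
#'
#' @param n Number of children.
#' @param prevalence Probability that a child carries label 1 (likely
#'   fine-motor problems). Must lie strictly in (0, 1).
#' @param seed Integer seed; the cohort is a pure function of its arguments.
#' @param config Mixture parameters, see [cohort_config()].
#' @return Tibble with columns `id`, `age` (years), `gender`
#'   (`"girl"`/`"boy"`), `skill` (latent, in `[0,1]`), `game_skill`
#'   (latent, in `[0,1]`), `percentile` (0-100) and `label` (0/1).
#' @examples
#' sample_cohort(5, prevalence = 0.5, seed = 1)
#' @export
sample_cohort <- function(n, prevalence = 0.5, seed = 1L,
                          config = cohort_config()) {
  if (prevalence <= 0 || prevalence >= 1) {
    stop("`prevalence` must lie strictly in (0, 1)")
  }
  stopifnot(n >= 0)
  if (n == 0) {
    return(tibble::tibble(id = character(), age = numeric(),
                          gender = character(), skill = numeric(),
                          game_skill = numeric(), percentile = integer(),
                          label = integer()))
  }
  cut <- skill_cutoff()
  withr::with_seed(seed, {
    label <- stats::rbinom(n, 1L, prevalence)
    skill <- vapply(label, function(l) {
      if (l == 1L) rnorm_trunc(config$low_mean, config$low_sd, 0, cut)
      else rnorm_trunc(config$typical_mean, config$typical_sd, cut, 1)
    }, numeric(1))
    tibble::tibble(
      id = sprintf("child%03d", seq_len(n)),
      age = stats::runif(n, config$age_range[1], config$age_range[2]),
      gender = ifelse(stats::runif(n) < config$girl_prob, "girl", "boy"),
      skill = skill,
      game_skill = pmin(1, pmax(0, skill + stats::rnorm(n, 0, config$game_skill_sd))),
      percentile = skill_to_percentile(skill),
      label = as.integer(label)
    )
  })
}

# rejection sampler for a truncated normal; bounds half-open [lo, hi)
rnorm_trunc <- function(mean, sd, lo, hi) {
  for (i in 1:10000) {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lo && x < hi) return(x)
  }
  stop("truncated normal rejection sampler failed to converge")
}

#' Control model implied by a latent skill
#'
#' Maps skill to the virtual child's hand-control parameters. Every
#' parameter is a monotone function of `1 - skill`: less skilled children
#' react later, correct more weakly, wobble and jitter more, and slip off
#' the maze track more often.
#'
#' @param skill Latent skill in `[0, 1]`.
#' @return Named list: `gain` (1/s), `latency` (s), `wobble_sd` (rad/s),
#'   `jitter_sd` (m/s^2), `maze_error_rate` (per attempted step),
#'   `maze_recovery` (per control tick).
#' @export
control_model <- function(skill) {
  stopifnot(skill >= 0, skill <= 1)
  list(
    gain = 2.0 + 6.0 * skill,
    latency = 0.35 - 0.25 * skill,
    wobble_sd = 0.9 * (1 - skill),
    jitter_sd = 1.5 * (1 - skill),
    maze_error_rate = 0.13 * (1 - skill),
    maze_recovery = 0.5 + 0.4 * skill
  )
}

#' Maze-session control model
#'
#' In the self-paced precision game children compensate for weaker control
#' by slowing down, so the skill-dependent share of every imperfection is
#' compressed toward a skill-independent baseline: careful play still
#' wobbles and still slips at corners, roughly as much for everyone. This
#' is what makes the precision game a much weaker skill readout than the
#' paced speed game.
#'
#' @param skill Latent in-game ability in `[0, 1]`.
#' @return Named list with the same elements as [control_model()].
#' @export
maze_control_model <- function(skill) {
  stopifnot(skill >= 0, skill <= 1)
  base <- control_model(skill)
  list(
    gain = base$gain,
    latency = base$latency,
    wobble_sd = 0.25 + 0.20 * (1 - skill),
    jitter_sd = 0.50 + 0.45 * (1 - skill),
    maze_error_rate = 0.05 + 0.08 * (1 - skill),
    maze_recovery = base$maze_recovery
  )
}

#' Simulate one child playing one game
#'
#' Produces the paired sensor stream and event log for a session. The game
#' engine supplies the dot trajectory (roadrunner) or consumes the child's
#' attempted moves (maze); the child's hands are simulated as a delayed
#' proportional orientation controller with band-limited wobble, driven at
#' the IMU rate. The accelerometer reports gravity in the body frame plus
#' translational jitter; the gyroscope reports the true angular velocity
#' plus measurement noise. Outputs are clipped to the sensor ranges
#' (±8 G, ±2000 dps).
#'
#' Session-to-session variability beyond skill is modelled by log-normal
#' multipliers (sd 0.25 on the log scale) applied to the wobble, jitter and
#' maze-error parameters, drawn from the session seed.
#'
#' @param child One-row tibble as returned by [sample_cohort()].
#' @param game `"roadrunner"` or `"maze"`.
#' @param schedule Level schedule; defaults to a seed-chosen permutation for
#'   roadrunner and the fixed maze schedule.
#' @param seed Integer session seed.
#' @param noise Set `FALSE` to disable wobble, jitter, sensor noise and the
#'   session-level multipliers (used for ground-truth checks).
#' @param topo A `cube_topology`.
#' @return A `game_session`: list with `stream` (tibble
#'   `t, ax, ay, az, gx, gy, gz`, SI units), `log` (a `session_log`),
#'   `truth` (tibble `t, align`: the simulator's internally known
#'   dot-to-up cosine alignment), `child`, and `rotation` (final pose).
#' @export
simulate_session <- function(child, game = c("roadrunner", "maze"),
                             schedule = NULL, seed = 1L, noise = TRUE,
                             topo = cube_topology()) {
  game <- match.arg(game)
  stopifnot(nrow(child) == 1)
  if (is.null(schedule)) {
    schedule <- if (game == "roadrunner") {
      roadrunner_schedule(derive_seed(seed, 1) %% 10L)
    } else {
      maze_schedule()
    }
  }
  validate_schedule(schedule, game)
  # hands are driven by the in-game ability where the cohort provides one
  ability <- child$game_skill %||% child$skill
  ctrl <- if (game == "maze") maze_control_model(ability) else
    control_model(ability)
  engine_seed <- derive_seed(seed, 2)
  noise_seed <- derive_seed(seed, 3)

  withr::with_seed(noise_seed, {
    # session-level variability: paced tracking is fairly repeatable, while
    # self-paced precision play varies a lot from one session to the next
    mult_sd <- if (game == "maze") c(0.5, 0.5, 0.6) else c(0.25, 0.25, 0.4)
    mult <- if (noise) exp(stats::rnorm(3, 0, mult_sd)) else c(1, 1, 1)
    wobble_sd <- if (noise) ctrl$wobble_sd * mult[1] else 0
    jitter_sd <- if (noise) ctrl$jitter_sd * mult[2] else 0
    err_rate <- if (noise) min(0.9, ctrl$maze_error_rate * mult[3]) else
      control_model(ability)$maze_error_rate

    log <- if (game == "roadrunner") {
      run_roadrunner(schedule, engine_seed, child$id, topo)
    } else {
      run_maze(schedule, maze_controller(err_rate, ctrl$maze_recovery),
               engine_seed, child$id, topo)
    }

    total <- schedule_total(schedule)
    n <- round(total * IMU_RATE)
    t <- (seq_len(n) - 1) / IMU_RATE
    dt <- 1 / IMU_RATE

    if (game == "roadrunner") {
      lag_cell <- dot_cell_at(log, pmax(t - ctrl$latency, 0))
      cur_cell <- dot_cell_at(log, t)
      # the planned target is smoothed at the motor bandwidth: hands do not
      # produce step commands when the dot jumps to the next cell
      target_body <- smooth_direction(topo$centers[lag_cell + 1L, , drop = FALSE],
                                      MOTOR_BANDWIDTH, IMU_RATE)
      target_world <- matrix(rep(c(0, 0, 1), each = n), n, 3)
      align_body <- topo$centers[cur_cell + 1L, , drop = FALSE]
    } else {
      # maze tilt model: the child rocks the cube's top face toward the
      # direction of the intended step; the azimuth follows progress along
      # the loop, lagged by the reaction latency
      phase <- maze_tilt_phase(log, pmax(t - ctrl$latency, 0), topo)
      tilt <- 20 * pi / 180
      target_world <- smooth_direction(
        cbind(sin(tilt) * cos(phase), sin(tilt) * sin(phase),
              rep(cos(tilt), n)),
        MOTOR_BANDWIDTH, IMU_RATE
      )
      target_body <- matrix(rep(c(0, 0, 1), each = n), n, 3)
      align_body <- target_body
    }

    wobble <- band_limited_noise(n, 3, wobble_sd, corner = 2, rate = IMU_RATE)
    jitter <- matrix(stats::rnorm(3 * n, 0, jitter_sd), n, 3)
    gyro_noise <- if (noise) matrix(stats::rnorm(3 * n, 0, 0.02), n, 3) else
      matrix(0, n, 3)

    res <- .integrate_controller(target_body, target_world, align_body,
                                 wobble, jitter, gyro_noise,
                                 ctrl$gain, dt, GRAVITY, diag(3))
    accel <- clip_range(res$accel, ACCEL_LIMIT)
    gyro <- clip_range(res$gyro, GYRO_LIMIT)

    structure(
      list(
        stream = tibble::tibble(
          t = t, ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
          gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3]
        ),
        log = log,
        truth = tibble::tibble(t = t, align = res$align),
        child = child,
        rotation = res$rotation
      ),
      class = "game_session"
    )
  })
}

MOTOR_BANDWIDTH <- 1.5  # Hz: corner of the hand-command smoothing

# One-pole low-pass per column at the motor bandwidth, rows renormalised to
# unit vectors; initialised at the first value so there is no start-up
# transient.
smooth_direction <- function(mat, corner, rate) {
  a <- exp(-2 * pi * corner / rate)
  for (j in seq_len(ncol(mat))) {
    mat[, j] <- stats::filter((1 - a) * mat[, j], a, method = "recursive",
                              init = mat[1, j])
  }
  nrm <- sqrt(rowSums(mat^2))
  nrm[nrm == 0] <- 1
  mat / nrm
}

# Azimuth (rad) of the maze tilt target over time: proportional to the dot's
# position along the level-0 reference loop, held between moves.
maze_tilt_phase <- function(log, times, topo) {
  ev <- log$events[log$events$kind == "dot_move", ]
  idx <- findInterval(times, ev$t)
  idx[idx == 0L] <- 1L
  # progress counter: each move advances the phase by one loop step
  2 * pi * (idx %% 12L) / 12
}

# First-order low-pass filtered Gaussian noise, scaled so the stationary
# standard deviation equals `sd`. Part of its power sits below the analysis
# filter's 4 Hz cut-off by construction (corner 2 Hz).
band_limited_noise <- function(n, cols, sd, corner, rate) {
  if (sd <= 0) return(matrix(0, n, cols))
  a <- exp(-2 * pi * corner / rate)
  scale <- sqrt((1 - a)^2 / (1 - a^2))  # stationary sd of the AR(1) output
  white <- matrix(stats::rnorm(n * cols), n, cols)
  out <- matrix(0, n, cols)
  for (j in seq_len(cols)) {
    out[, j] <- stats::filter(white[, j] * (1 - a), a, method = "recursive")
  }
  out * sd / scale
}

#' @export
print.game_session <- function(x, ...) {
  cat("<game_session>", x$log$game, "child", x$child$id,
      "|", nrow(x$stream), "IMU samples at", IMU_RATE, "Hz\n")
  invisible(x)
}
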