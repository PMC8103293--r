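# Shared, lazily built fixtures. Sessions are expensive enough (110 Hz over
# four to five minutes) that tests share one simulated instance per need.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

fix_child <- function(skill, id = "fix", age = 7.5, gender = "girl") {
  tibble::tibble(id = id, age = age, gender = gender, skill = skill,
                 game_skill = skill,
                 percentile = motorcube:::skill_to_percentile(skill),
                 label = as.integer(motorcube:::skill_to_percentile(skill) <= 16))
}

# one mid-skill roadrunner session with noise, reused by feature tests
fix_rr_session <- function() {
  fixture("rr_session", function() {
    simulate_session(fix_child(0.6), "roadrunner",
                     schedule = roadrunner_schedule(0), seed = 42)
  })
}

# noise-free high-skill roadrunner session, reused by recovery tests
fix_rr_clean <- function() {
  fixture("rr_clean", function() {
    simulate_session(fix_child(0.9), "roadrunner",
                     schedule = roadrunner_schedule(0), seed = 7,
                     noise = FALSE)
  })
}

fix_maze_session <- function() {
  fixture("maze_session", function() {
    simulate_session(fix_child(0.5), "maze", seed = 42)
  })
}

# small labelled feature table with a perfectly separating feature, for
# classifier plumbing tests (no simulation involved)
fix_separable_features <- function(n = 18) {
  fixture("separable", function() {
    withr::with_seed(99, {
      label <- rep(c(1L, 0L), each = n / 2)
      tibble::tibble(
        id = sprintf("s%02d", seq_len(n)),
        f1 = label * 10 + stats::rnorm(n, 0, 0.1),
        f2 = label * 5 + stats::rnorm(n, 0, 0.1),
        age = stats::runif(n, 6.5, 9),
        gender = rep(c(0, 1), n / 2),
        label = label,
        game = "roadrunner", levels = "0+1+2"
      )
    })
  })
}

# cohort-scale feature tables for both games (built once; used by the
# acceptance label-recovery and null-calibration checks)
fix_cohort_tables <- function(seed) {
  fixture(paste0("cohort_tables_", seed), function() {
    cohort <- sample_cohort(95, 49 / 95, seed = seed)
    list(
      cohort = cohort,
      roadrunner = cohort_features(cohort, "roadrunner", seed = seed),
      maze = cohort_features(cohort, "maze", seed = seed)
    )
  })
}
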