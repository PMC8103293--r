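# Roadrunner game engine: the green dot advances on its own clock; the
# player's task (keeping the dot's face up) does not influence the dot, so
# the engine is a pure function of schedule and seed.

#' Run the roadrunner game
#'
#' Simulates the dot trajectory for one roadrunner session. The dot starts
#' at the middle cell of the top face heading toward +x and advances one
#' forward step every `delay(LoD)` seconds (moves fall at `t0 + k * delay`,
#' `k >= 1`; a move landing exactly on a segment boundary belongs to the
#' next segment). Whenever the dot sits on a face's middle cell, the next
#' move direction is drawn uniformly from left / right / straight on.
#'
#' @param schedule A roadrunner [roadrunner_schedule()].
#' @param seed Integer seed; identical seeds give identical logs.
#' @param child_id Identifier stored in the log.
#' @param topo A `cube_topology`.
#' @return A `session_log`: list with `child_id`, `game`, `schedule`,
#'   `permutation`, `seed` and `events`, a tibble with columns
#'   `t` (s), `kind` (`level_start`, `dot_move`, `session_end`), `cell`,
#'   `lod`, `warmup`. A `dot_move` at t = 0 records the initial placement.
#' @export
run_roadrunner <- function(schedule, seed = 1L, child_id = "anon",
                           topo = cube_topology()) {
  validate_schedule(schedule, "roadrunner")
  win <- schedule_windows(schedule)
  withr::with_seed(seed, {
    cell <- topo$middle[1]   # middle of the top face
    heading <- 0L            # +u of face 0, i.e. +x
    t <- c(0); kind <- c("dot_move"); cells <- c(cell)
    lods <- c(win$lod[1]); warm <- c(TRUE)
    for (i in seq_len(nrow(win))) {
      t <- c(t, win$t0[i]); kind <- c(kind, "level_start")
      cells <- c(cells, NA_integer_); lods <- c(lods, win$lod[i])
      warm <- c(warm, win$warmup[i])
      delay <- schedule$delays[[as.character(win$lod[i])]]
      # largest k with k*delay strictly inside the segment; a move landing
      # exactly on the boundary belongs to the next segment
      n_moves <- floor((win$duration[i] - 1e-9) / delay)
      if (n_moves > 0) {
        mt <- win$t0[i] + seq_len(n_moves) * delay
        mc <- integer(n_moves)
        for (k in seq_len(n_moves)) {
          if (cell %in% topo$middle) {
            turn <- sample(c("left", "right", "forward"), 1L)
            if (turn != "forward") {
              heading <- turn_heading(cell, heading, turn, topo)
            }
          }
          s <- forward_step(cell, heading, topo)
          cell <- s$cell; heading <- s$heading
          mc[k] <- cell
        }
        t <- c(t, mt); kind <- c(kind, rep("dot_move", n_moves))
        cells <- c(cells, mc); lods <- c(lods, rep(win$lod[i], n_moves))
        warm <- c(warm, rep(win$warmup[i], n_moves))
      }
    }
    total <- schedule_total(schedule)
    events <- tibble::tibble(
      t = c(t, total), kind = c(kind, "session_end"),
      cell = c(cells, NA_integer_), lod = c(lods, NA_integer_),
      warmup = c(warm, FALSE)
    )
    events <- dplyr::arrange(events, t, match(kind, c("level_start", "dot_move",
                                                      "session_end")))
    new_session_log(child_id, "roadrunner", schedule, events, seed)
  })
}

new_session_log <- function(child_id, game, schedule, events, seed) {
  structure(
    list(
      child_id = child_id, game = game, schedule = schedule,
      permutation = schedule$permutation, seed = as.integer(seed),
      events = events
    ),
    class = "session_log"
  )
}

#' @export
print.session_log <- function(x, ...) {
  cat("<session_log> child", x$child_id, "game", x$game,
      "|", nrow(x$events), "events over",
      format(schedule_total(x$schedule)), "s\n")
  invisible(x)
}

# Piecewise-constant dot cell at arbitrary query times (roadrunner & maze).
dot_cell_at <- function(log, times) {
  ev <- log$events[log$events$kind == "dot_move", ]
  if (nrow(ev) == 0L) stop("log contains no dot_move events")
  idx <- findInterval(times, ev$t)
  if (any(idx == 0L)) stop("query time precedes the first dot placement")
  ev$cell[idx]
}
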