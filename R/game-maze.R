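# Maze game engine: the white dot is player-driven. The engine owns the
# track layout and the on/off-path bookkeeping; a controller supplies the
# attempted moves at the fixed control cadence (one attempted step per
# 0.3 s, matching a tilt-driven control law rate limit).

MAZE_STEP_PERIOD <- 0.3

# Frozen track definitions: a start state and a forward/left/right
# instruction string, expanded against the topology at build time.
# Level 0: the equatorial band through the middle cells of four faces, so
# every face crossing happens at the middle of a side. Level 1: a staircase
# meander that crosses several face edges away from the middle of the side.
.maze_tracks <- list(
  `0` = list(cell = 4L, heading = 0L, moves = strsplit("FFFFFFFFFFFF", "")[[1]]),
  `1` = list(cell = 0L, heading = 0L,
             moves = strsplit("FRFLFRFLFRFLFRFLFRFLFRFL", "")[[1]])
)

#' Build a maze track layout
#'
#' Expands the frozen track definition for a difficulty level into an
#' ordered closed loop of cells. The loop is infinite in play: after the
#' last path cell the dot continues at the first. Cells off the loop are
#' blocked (they light up as walls); stepping onto one flags the dot as
#' off-path until it returns.
#'
#' @param lod Difficulty level, 0 (crossings only at side middles) or 1
#'   (crossings also at edge cells away from the middle).
#' @param topo A `cube_topology`.
#' @return A `maze_layout`: list with `lod`, `path_cells` (ordered, closed:
#'   consecutive cells and last-to-first are forward-adjacent) and
#'   `blocked_cells` (all remaining cells).
#' @export
maze_layout <- function(lod, topo = cube_topology()) {
  if (!length(lod) == 1L || !lod %in% c(0L, 1L)) {
    stop("`lod` must be 0 or 1")
  }
  def <- .maze_tracks[[as.character(lod)]]
  cell <- def$cell; heading <- def$heading
  path <- integer(0)
  for (mv in def$moves) {
    path <- c(path, cell)
    if (mv == "L") heading <- turn_heading(cell, heading, "left", topo)
    if (mv == "R") heading <- turn_heading(cell, heading, "right", topo)
    s <- forward_step(cell, heading, topo)
    cell <- s$cell; heading <- s$heading
  }
  if (cell != def$cell) stop("internal error: maze track does not close")
  structure(
    list(lod = as.integer(lod), path_cells = path,
         blocked_cells = setdiff(0:53, path)),
    class = "maze_layout"
  )
}

# All four forward-neighbours of a cell (one per heading).
cell_neighbours <- function(cell, topo = cube_topology()) {
  vapply(0:3, function(h) forward_step(cell, h, topo)$cell, integer(1))
}

#' Run the maze game
#'
#' Drives one maze session from a controller. Control ticks occur every
#' 0.3 s; at each tick the controller may attempt one step to an adjacent
#' cell. Stepping off the track emits `off_path_enter` (the dot turns red),
#' stepping back onto it emits `off_path_exit`, so the on/off-path state is
#' reconstructible from the event stream at any time. At each level start
#' the dot is reset to the first path cell of that level's layout.
#'
#' @param schedule A [maze_schedule()].
#' @param controller Function `(t, state)` returning the attempted target
#'   cell for this tick, or `NA` to stay put. `state` is a list with
#'   `cell` (current), `on_path`, `target` (next path cell in loop order
#'   while on path, the re-entry cell while off path), `layout`, and `topo`.
#' @param seed Integer seed, exposed to the controller via the RNG.
#' @param child_id Identifier stored in the log.
#' @param topo A `cube_topology`.
#' @return A `session_log` (see [run_roadrunner()]); `dot_move` events carry
#'   the dot cell, `off_path_enter`/`off_path_exit` mark track excursions.
#' @export
run_maze <- function(schedule, controller = maze_controller(0), seed = 1L,
                     child_id = "anon", topo = cube_topology()) {
  validate_schedule(schedule, "maze")
  win <- schedule_windows(schedule)
  layouts <- list(`0` = maze_layout(0L, topo), `1` = maze_layout(1L, topo))
  withr::with_seed(seed, {
    t <- numeric(0); kind <- character(0); cells <- integer(0)
    lods <- integer(0); warm <- logical(0)
    emit <- function(tt, kk, cc, ll, ww) {
      t <<- c(t, tt); kind <<- c(kind, kk); cells <<- c(cells, cc)
      lods <<- c(lods, ll); warm <<- c(warm, ww)
    }
    prev_off <- FALSE
    for (i in seq_len(nrow(win))) {
      layout <- layouts[[as.character(win$lod[i])]]
      path <- layout$path_cells
      cell <- path[1]; pos <- 1L; on_path <- TRUE; reentry <- path[1]
      if (prev_off) {
        # the level reset puts the dot back on the track; close the open
        # excursion so enter/exit events keep alternating
        emit(win$t0[i], "off_path_exit", cell, win$lod[i], win$warmup[i])
      }
      emit(win$t0[i], "level_start", NA_integer_, win$lod[i], win$warmup[i])
      emit(win$t0[i], "dot_move", cell, win$lod[i], win$warmup[i])
      ticks <- win$t0[i] + seq_len(floor((win$duration[i] - 1e-9) / MAZE_STEP_PERIOD)) *
        MAZE_STEP_PERIOD
      for (tt in ticks) {
        target <- if (on_path) path[pos %% length(path) + 1L] else reentry
        attempt <- controller(tt, list(cell = cell, on_path = on_path,
                                       target = target, layout = layout,
                                       topo = topo))
        if (is.na(attempt) || attempt == cell) next
        if (!attempt %in% cell_neighbours(cell, topo)) {
          stop("controller attempted a non-adjacent step")
        }
        was_on <- on_path
        cell <- attempt
        on_path <- cell %in% path
        emit(tt, "dot_move", cell, win$lod[i], win$warmup[i])
        if (was_on && !on_path) {
          reentry <- path[pos]  # come back where you left
          emit(tt, "off_path_enter", cell, win$lod[i], win$warmup[i])
        } else if (!was_on && on_path) {
          emit(tt, "off_path_exit", cell, win$lod[i], win$warmup[i])
        }
        if (on_path) pos <- match(cell, path)
      }
      prev_off <- !on_path
    }
    total <- schedule_total(schedule)
    emit(total, "session_end", NA_integer_, NA_integer_, FALSE)
    events <- tibble::tibble(t = t, kind = kind, cell = cells, lod = lods,
                             warmup = warm)
    new_session_log(child_id, "maze", schedule, events, seed)
  })
}

#' Maze controller with a tunable error rate
#'
#' Models a child steering the dot along the track: while on the path it
#' moves toward the next path cell but, with probability `error_rate`,
#' slips to a uniformly drawn wrong neighbour instead; while off the path
#' it steers back to the re-entry cell, with probability `recovery` per
#' tick (slips prolong the excursion).
#'
#' @param error_rate Probability per attempted step of a wrong move.
#' @param recovery Probability per tick of moving back while off-path.
#' @return A controller function for [run_maze()].
#' @export
maze_controller <- function(error_rate = 0, recovery = 0.7) {
  force(error_rate); force(recovery)
  function(t, state) {
    if (!state$on_path) {
      if (stats::runif(1) < recovery) return(state$target)
      return(NA_integer_)
    }
    if (error_rate > 0 && stats::runif(1) < error_rate) {
      wrong <- setdiff(cell_neighbours(state$cell, state$topo), state$target)
      return(wrong[sample.int(length(wrong), 1L)])
    }
    state$target
  }
}
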