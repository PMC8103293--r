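# Level schedules for the two games.
#
# Roadrunner: six 30 s segments drawn from difficulty levels {0,1,2}, each
# level twice, starting at level 0, no immediate repeats; the level sets the
# dot's dwell delay d in {0.8, 0.6, 0.4} s. Maze: four 60 s segments with
# levels (0,1,0,1). Both games open with a 60 s warm-up that is flagged so
# feature extraction can drop it.

.roadrunner_delays <- c(`0` = 0.8, `1` = 0.6, `2` = 0.4)

#' Enumerate all admissible roadrunner level orderings
#'
#' All length-6 sequences over levels \{0,1,2\} in which every level appears
#' exactly twice, the first segment is level 0 (every player starts on the
#' easiest level) and no two adjacent segments share a level. There are
#' exactly 10 such orderings.
#'
#' @return A tibble with columns `permutation` (id 0..9) and `lod1`..`lod6`,
#'   rows in lexicographic order.
#' @examples
#' roadrunner_permutations()
#' @export
roadrunner_permutations <- function() {
  grid <- as.matrix(expand.grid(rep(list(0:2), 6))[, 6:1])
  keep <- grid[, 1] == 0 &
    apply(grid, 1, function(s) all(tabulate(s + 1L, 3L) == 2L)) &
    apply(grid, 1, function(s) all(diff(s) != 0L))
  seqs <- grid[keep, , drop = FALSE]
  seqs <- seqs[do.call(order, as.data.frame(seqs)), , drop = FALSE]
  colnames(seqs) <- paste0("lod", 1:6)
  dplyr::bind_cols(
    tibble::tibble(permutation = seq_len(nrow(seqs)) - 1L),
    tibble::as_tibble(seqs)
  )
}

#' Roadrunner level schedule
#'
#' @param permutation Either a permutation id in 0..9 (row of
#'   [roadrunner_permutations()]) or an explicit length-6 level sequence.
#' @return A `level_schedule`: list with `game`, `segments` (tibble
#'   `lod`, `duration`, `warmup`), `warmup_duration`, and `delays`
#'   (level -> dwell seconds, roadrunner only).
#' @export
roadrunner_schedule <- function(permutation = 0L) {
  if (length(permutation) == 1L) {
    perms <- roadrunner_permutations()
    if (!permutation %in% perms$permutation) {
      stop("`permutation` must be an id in 0..9 or a length-6 level sequence")
    }
    lods <- as.integer(perms[perms$permutation == permutation, -1])
    perm_id <- as.integer(permutation)
  } else {
    lods <- as.integer(permutation)
    perm_id <- NA_integer_
    valid <- length(lods) == 6L && lods[1] == 0L &&
      all(tabulate(lods + 1L, 3L) == 2L) && all(diff(lods) != 0L)
    if (!valid) stop("invalid roadrunner level sequence")
  }
  structure(
    list(
      game = "roadrunner",
      segments = tibble::tibble(
        lod = c(0L, lods),
        duration = c(60, rep(30, 6)),
        warmup = c(TRUE, rep(FALSE, 6))
      ),
      warmup_duration = 60,
      delays = .roadrunner_delays,
      permutation = perm_id
    ),
    class = "level_schedule"
  )
}

#' Maze level schedule
#'
#' The maze has two levels; they alternate (0, 1, 0, 1) for 60 s each after
#' the 60 s warm-up, so no ordering randomisation is possible.
#'
#' @return A `level_schedule` (see [roadrunner_schedule()]).
#' @export
maze_schedule <- function() {
  structure(
    list(
      game = "maze",
      segments = tibble::tibble(
        lod = c(0L, 0L, 1L, 0L, 1L),
        duration = c(60, rep(60, 4)),
        warmup = c(TRUE, rep(FALSE, 4))
      ),
      warmup_duration = 60,
      delays = NULL,
      permutation = NA_integer_
    ),
    class = "level_schedule"
  )
}

# Segment boundaries as a tibble with t0/t1 (seconds from session start).
schedule_windows <- function(schedule) {
  seg <- schedule$segments
  t1 <- cumsum(seg$duration)
  dplyr::mutate(seg, t0 = t1 - seg$duration, t1 = t1)
}

schedule_total <- function(schedule) sum(schedule$segments$duration)

validate_schedule <- function(schedule, game) {
  if (!inherits(schedule, "level_schedule") || schedule$game != game) {
    stop("expected a ", game, " `level_schedule`")
  }
  invisible(schedule)
}
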