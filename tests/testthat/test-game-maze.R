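test_that("both maze tracks are simple closed loops under the topology", {
  topo <- cube_topology()
  for (lod in 0:1) {
    lay <- maze_layout(lod, topo)
    path <- lay$path_cells
    expect_true(all(path %in% 0:53))
    expect_equal(anyDuplicated(path), 0)
    for (k in seq_along(path)) {
      nxt <- path[k %% length(path) + 1]
      nb <- vapply(0:3, function(h) forward_step(path[k], h, topo)$cell,
                   integer(1))
      expect_true(nxt %in% nb)
    }
    expect_setequal(c(path, lay$blocked_cells), 0:53)
  }
  expect_error(maze_layout(2), "lod")
})

# in-face offset of `cell` along the edge it crosses toward `nxt`
edge_offset <- function(cell, nxt) {
  f1 <- cell %/% 9; f2 <- nxt %/% 9
  if (f1 == f2) return(NA_real_)
  u <- motorcube:::.face_u[f1 + 1, ]; v <- motorcube:::.face_v[f1 + 1, ]
  n2 <- motorcube:::.face_normals[f2 + 1, ]
  a <- cell %% 3 - 1; b <- (cell %% 9) %/% 3 - 1
  off <- a * u + b * v
  # component perpendicular to the crossing direction = position along edge
  perp <- off - sum(off * n2) * n2
  sqrt(sum(perp^2))
}

test_that("level 0 crosses faces at side middles, level 1 also at edges", {
  for (lod in 0:1) {
    lay <- maze_layout(lod)
    path <- lay$path_cells
    offs <- c()
    for (k in seq_along(path)) {
      o <- edge_offset(path[k], path[k %% length(path) + 1])
      if (!is.na(o)) offs <- c(offs, o)
    }
    expect_gt(length(offs), 0)
    if (lod == 0) expect_true(all(offs == 0)) else expect_true(any(offs > 0))
  }
})

test_that("a perfect path-follower never leaves the track", {
  log <- run_maze(maze_schedule(), maze_controller(0), seed = 1)
  expect_equal(sum(log$events$kind == "off_path_enter"), 0)
  expect_equal(sum(log$events$kind == "off_path_exit"), 0)
  expect_true(all(maze_ok_signal(log, seq(0, 299.9, by = 0.1)) == 1))
})

test_that("leaving the track once and never returning logs a single enter", {
  runaway <- local({
    left <- FALSE
    function(t, state) {
      if (state$on_path && !left) {
        left <<- TRUE
        wrong <- setdiff(motorcube:::cell_neighbours(state$cell, state$topo),
                         state$target)
        return(wrong[wrong %in% state$layout$blocked_cells][1])
      }
      NA_integer_
    }
  })
  # single-segment schedule so the level reset cannot pull the dot back
  sch <- maze_schedule()
  sch$segments <- sch$segments[1, ]
  log <- run_maze(sch, runaway, seed = 2)
  expect_equal(sum(log$events$kind == "off_path_enter"), 1)
  expect_equal(sum(log$events$kind == "off_path_exit"), 0)
  ok <- maze_ok_signal(log, c(0, 59))
  expect_equal(ok[1], 1L)
  expect_equal(ok[2], 0L)
})

test_that("off-path events strictly alternate in noisy sessions", {
  for (seed in 1:5) {
    log <- run_maze(maze_schedule(), maze_controller(0.4, recovery = 0.5),
                    seed = seed)
    ev <- log$events$kind[log$events$kind %in% c("off_path_enter",
                                                 "off_path_exit")]
    expect_gt(length(ev), 0)
    expect_equal(ev, rep(c("off_path_enter", "off_path_exit"),
                         length.out = length(ev)))
  }
})

test_that("maze logs are deterministic given seed", {
  a <- run_maze(maze_schedule(), maze_controller(0.3), seed = 8)
  b <- run_maze(maze_schedule(), maze_controller(0.3), seed = 8)
  expect_identical(a$events, b$events)
})
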