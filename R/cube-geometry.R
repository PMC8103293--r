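# Surface model of the 54-LED cube: 6 faces x 9 cells, indexed 0..53.
#
# Face order: 0 = +z (top), 1 = +x, 2 = -z, 3 = -x, 4 = +y, 5 = -y.
# Within a face, cells are row-major as seen from outside the cube:
# cell = 9*face + 3*row + col, row/col in {0,1,2}; "col" grows along the
# face's u axis, "row" along its v axis (u x v points into the cube, so u
# is "right" and v is "down" for an outside viewer).

.face_normals <- rbind(
  c(0, 0, 1), c(1, 0, 0), c(0, 0, -1), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0)
)
.face_u <- rbind(
  c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(0, 1, 0), c(1, 0, 0), c(1, 0, 0)
)
.face_v <- rbind(
  c(0, -1, 0), c(0, 0, -1), c(0, 1, 0), c(0, 0, 1), c(0, 0, 1), c(0, 0, -1)
)

#' Build the cube surface topology
#'
#' Constructs the fixed topology of the toy's 54-cell LED surface: face
#' membership, unit cell-center direction per cell (body frame), and the
#' forward/turn transition tables over the 216 (cell, heading) states.
#'
#' A heading is an integer in 0..3 indexing the four in-face travel
#' directions `(+u, +v, -u, -v)` of the cell's face. Walking forward off a
#' face edge rolls onto the neighbouring face; the heading is re-expressed
#' in that face's basis (it becomes the reversed normal of the face left
#' behind), so "keep moving forward" is well defined everywhere.
#'
#' @return An object of class `cube_topology`: a list with
#'   `centers` (54 x 3 matrix of unit vectors, row i+1 is cell i),
#'   `face` (integer vector, face id 0..5 per cell),
#'   `normals` (6 x 3 face normal matrix),
#'   `forward` (length-216 integer vector: forward map over state ids
#'   `4*cell + heading`, zero-based),
#'   `turn_left`, `turn_right` (6 x 4 matrices: new heading by face and
#'   heading), and `middle` (the six face-middle cell ids).
#' @examples
#' topo <- cube_topology()
#' topo$face[1]    # cell 0 lies on face 0
#' topo$centers[5, ]  # middle cell of the top face points straight up
#' @export
cube_topology <- function() {
  if (!is.null(.motorcube_cache$topology)) {
    return(.motorcube_cache$topology)
  }
  face <- rep(0:5, each = 9L)
  # Lattice points doubled so everything stays integer: 2P = 3n + 2a u + 2b v,
  # with in-face offsets a = col-1, b = row-1.
  centers <- matrix(0, 54, 3)
  for (cell in 0:53) {
    f <- cell %/% 9L
    r <- (cell %% 9L) %/% 3L
    c_ <- cell %% 3L
    p <- 1.5 * .face_normals[f + 1, ] +
      (c_ - 1L) * .face_u[f + 1, ] + (r - 1L) * .face_v[f + 1, ]
    centers[cell + 1, ] <- p / sqrt(sum(p^2))
  }

  dirs <- function(f) {
    rbind(.face_u[f + 1, ], .face_v[f + 1, ], -.face_u[f + 1, ], -.face_v[f + 1, ])
  }
  match_dir <- function(f, h3) {
    d <- dirs(f)
    which(colSums(abs(t(d) - h3)) == 0) - 1L
  }
  face_of_normal <- function(n3) {
    which(colSums(abs(t(.face_normals) - n3)) == 0) - 1L
  }

  forward <- integer(216)
  for (cell in 0:53) {
    f <- cell %/% 9L
    a <- cell %% 3L - 1L
    b <- (cell %% 9L) %/% 3L - 1L
    u <- .face_u[f + 1, ]; v <- .face_v[f + 1, ]; n <- .face_normals[f + 1, ]
    for (h in 0:3) {
      h3 <- dirs(f)[h + 1, ]
      a2 <- a + sum(h3 * u)
      b2 <- b + sum(h3 * v)
      if (abs(a2) <= 1 && abs(b2) <= 1) {
        ncell <- 9L * f + 3L * (b2 + 1L) + (a2 + 1L)
        nh <- h
      } else {
        f2 <- face_of_normal(h3)
        # in-face offset perpendicular to travel is carried across the edge;
        # the arrival row hugs the shared edge (offset n from face 2's center)
        w <- (a * u + b * v) - sum((a * u + b * v) * h3) * h3
        pos <- n + w
        a2 <- sum(pos * .face_u[f2 + 1, ])
        b2 <- sum(pos * .face_v[f2 + 1, ])
        ncell <- 9L * f2 + 3L * (b2 + 1L) + (a2 + 1L)
        nh <- match_dir(f2, -n)
      }
      forward[4L * cell + h + 1L] <- 4L * ncell + nh
    }
  }
  forward <- as.integer(round(forward))

  turn_left <- matrix(0L, 6, 4)
  turn_right <- matrix(0L, 6, 4)
  for (f in 0:5) {
    n <- .face_normals[f + 1, ]
    for (h in 0:3) {
      h3 <- dirs(f)[h + 1, ]
      turn_left[f + 1, h + 1] <- match_dir(f, .cross3(n, h3))
      turn_right[f + 1, h + 1] <- match_dir(f, .cross3(h3, n))
    }
  }

  topo <- structure(
    list(
      centers = centers, face = face, normals = .face_normals,
      forward = forward, turn_left = turn_left, turn_right = turn_right,
      middle = 9L * (0:5) + 4L
    ),
    class = "cube_topology"
  )
  .motorcube_cache$topology <- topo
  topo
}

.motorcube_cache <- new.env(parent = emptyenv())

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2], a[3] * b[1] - a[1] * b[3], a[1] * b[2] - a[2] * b[1])
}

#' Advance one forward step on the cube surface
#'
#' @param cell Cell index in 0..53.
#' @param heading Heading id in 0..3 (see [cube_topology()]).
#' @param topo A `cube_topology`.
#' @return List with elements `cell` and `heading` after one forward step.
#' @export
forward_step <- function(cell, heading, topo = cube_topology()) {
  stopifnot(cell %in% 0:53, heading %in% 0:3)
  s <- topo$forward[4L * cell + heading + 1L]
  list(cell = s %/% 4L, heading = s %% 4L)
}

#' Turn a heading left or right within its face
#'
#' @inheritParams forward_step
#' @param side `"left"` or `"right"`.
#' @return The new heading id.
#' @export
turn_heading <- function(cell, heading, side = c("left", "right"),
                         topo = cube_topology()) {
  side <- match.arg(side)
  f <- cell %/% 9L
  tab <- if (side == "left") topo$turn_left else topo$turn_right
  tab[f + 1L, heading + 1L]
}

#' Cosine alignment between a cell and the up direction
#'
#' Cosine of the angle between the cell-center direction of `cell` and the
#' world up direction expressed in the cube body frame. Ranges over
#' \eqn{[-1, 1]}: 1 when the cell sits exactly on top of the cube, -1 when it
#' is underneath, 0 when it faces sideways.
#'
#' @param cell Cell index in 0..53 (vectorised).
#' @param up_body Unit 3-vector: world up expressed in the body frame, or an
#'   `n x 3` matrix of such vectors (one per cell entry).
#' @param topo A `cube_topology`.
#' @param tol Tolerance on `|up_body| - 1` before an error is raised.
#' @return Numeric vector of cosine similarities in `[-1, 1]`.
#' @export
alignment <- function(cell, up_body, topo = cube_topology(), tol = 1e-6) {
  stopifnot(all(cell %in% 0:53))
  if (is.null(dim(up_body))) up_body <- matrix(up_body, nrow = 1)
  nrm <- sqrt(rowSums(up_body^2))
  if (any(abs(nrm - 1) > tol)) {
    stop("`up_body` must have unit norm (max |norm - 1| = ",
         format(max(abs(nrm - 1))), ")")
  }
  ctr <- topo$centers[cell + 1L, , drop = FALSE]
  if (nrow(up_body) == 1L && nrow(ctr) > 1L) {
    up_body <- up_body[rep(1L, nrow(ctr)), , drop = FALSE]
  }
  pmin(1, pmax(-1, rowSums(ctr * up_body)))
}

#' Which face is pointing up
#'
#' Given a body-to-world rotation, returns the face whose rotated outward
#' normal has the largest world-z component. Exact ties (e.g. a 45 degree
#' pose) resolve to the lowest face id, so the result is deterministic.
#'
#' @param rotation 3 x 3 proper rotation matrix mapping body to world
#'   coordinates (world up is +z).
#' @param topo A `cube_topology`.
#' @return Face id in 0..5.
#' @export
up_face <- function(rotation, topo = cube_topology()) {
  stopifnot(is.matrix(rotation), all(dim(rotation) == c(3, 3)))
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6 || det(rotation) < 0) {
    stop("`rotation` must be a proper rotation matrix")
  }
  z <- rotation %*% t(topo$normals)  # world coords of the six normals
  which.max(round(z[3, ], 12)) - 1L  # round so exact ties break by face id
}
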