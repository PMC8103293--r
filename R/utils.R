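# Small shared helpers.

# Derive a 32-bit sub-seed from a master seed and a stream index so that
# independent stages (cohort, sessions, folds) never share an RNG stream.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(stream)) %% 2147483647)
}

# Rotation about a unit axis by `angle` radians (Rodrigues).
rotation_about <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Geodesic angle (radians) between two rotations.
rotation_angle <- function(r1, r2 = diag(3)) {
  tr <- sum(diag(crossprod(r1, r2)))
  acos(pmin(1, pmax(-1, (tr - 1) / 2)))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# symmetric saturation, preserving matrix shape
clip_range <- function(x, limit) {
  x[x > limit] <- limit
  x[x < -limit] <- -limit
  x
}
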