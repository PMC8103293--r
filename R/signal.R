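# Signal primitives for the IMU pipeline: zero-phase low-pass filtering,
# per-sample vector magnitude, and numerical differentiation.

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth filter at a 4 Hz cut-off (the defaults), applied
#' forward and backward for zero phase, so the effective magnitude response
#' is the squared single-pass response. The input is extended by odd
#' reflection at both ends (about one second of padding) before filtering,
#' which suppresses the start-up transient that plain filtering would leak
#' into the first and last samples.
#'
#' @param x Numeric vector, or a matrix filtered column-wise.
#' @param rate Sampling rate in Hz; must exceed twice the cut-off.
#' @param cutoff Cut-off frequency in Hz.
#' @param order Butterworth order of the single pass.
#' @return Filtered signal, same shape as `x`.
#' @export
lowpass <- function(x, rate, cutoff = 4, order = 4) {
  if (is.matrix(x)) {
    return(apply(x, 2, lowpass, rate = rate, cutoff = cutoff, order = order))
  }
  if (rate <= 2 * cutoff) stop("`rate` must exceed twice the cut-off frequency")
  n <- length(x)
  minpad <- 3L * (order + 1L)
  if (n <= minpad) {
    stop("signal too short to filter (need more than ", minpad, " samples)")
  }
  pad <- min(n - 1L, max(minpad, as.integer(round(rate))))
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  ext <- c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  y <- signal::filter(bf, ext)
  y <- rev(as.numeric(signal::filter(bf, rev(as.numeric(y)))))
  y[(pad + 1):(pad + n)]
}

# Analytic magnitude response of the two-pass (zero-phase) Butterworth
# low-pass at frequency f: |H(f)|^2 with |H| the single-pass digital
# response. Used as the oracle for the filter tests.
lowpass_response <- function(f, rate, cutoff = 4, order = 4) {
  bf <- signal::butter(order, cutoff / (rate / 2), type = "low")
  z <- exp(-2i * pi * f / rate)
  h <- vapply(z, function(zz) {
    num <- sum(bf$b * zz^(0:(length(bf$b) - 1)))
    den <- sum(bf$a * zz^(0:(length(bf$a) - 1)))
    Mod(num / den)
  }, numeric(1))
  h^2
}

#' Euclidean magnitude of a tri-axial signal
#'
#' @param xyz An `n x 3` matrix (or three equal-length vectors via `...`).
#' @return Numeric vector of per-sample Euclidean norms.
#' @export
magnitude <- function(xyz) {
  if (!is.matrix(xyz) || ncol(xyz) != 3) stop("`xyz` must be an n x 3 matrix")
  sqrt(rowSums(xyz^2))
}

#' Numerical time derivative
#'
#' Central differences on the interior, one-sided differences at the two
#' endpoints, so the output has the same length as the input.
#'
#' @param x Numeric vector sampled uniformly.
#' @param rate Sampling rate in Hz.
#' @return The derivative of `x` in units of `x` per second.
#' @export
differentiate <- function(x, rate) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples to differentiate")
  d <- numeric(n)
  d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) * rate / 2
  d[1] <- (x[2] - x[1]) * rate
  d[n] <- (x[n] - x[n - 1]) * rate
  d
}
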