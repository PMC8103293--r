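# Paired Wilcoxon signed-rank test tailored to fold-wise score vectors,
# which are short, heavily tied and zero-laden. The exact null is computed
# by a convolution over sign assignments on (doubled, hence integer)
# average ranks, so ties need no approximation; larger samples use the
# normal approximation with continuity correction.

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired score vectors. Zero differences are
#' discarded before ranking (classic treatment; the Pratt variant, which
#' ranks them first and then drops them, is selectable); if every
#' difference is zero the test is degenerate and p = 1. Absolute
#' differences are ranked with average ranks. The exact null distribution
#' (all sign assignments equally likely) is evaluated when the number of
#' nonzero differences is at most `exact_max`, the normal approximation
#' with tie-corrected variance and continuity correction otherwise;
#' `method` can force either route.
#'
#' @param scores_a,scores_b Equal-length paired score vectors (>= 1 pair;
#'   meaningful from ~5).
#' @param zeroes `"discard"` (default) or `"pratt"`.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @param exact_max Largest number of nonzero differences for which
#'   `"auto"` picks the exact null.
#' @return List of class `wilcoxon_paired`: `statistic` (W+, sum of ranks
#'   of positive differences), `n_nonzero`, `method`, `p_value`.
#' @examples
#' wilcoxon_paired(c(1, 2, 3, 4, 5, 6), c(0, 1, 2, 3, 4, 5))$p_value
#' @export
wilcoxon_paired <- function(scores_a, scores_b,
                            zeroes = c("discard", "pratt"),
                            method = c("auto", "exact", "normal"),
                            exact_max = 25L) {
  zeroes <- match.arg(zeroes)
  method <- match.arg(method)
  if (length(scores_a) != length(scores_b)) {
    stop("paired score vectors must have equal length")
  }
  d <- scores_a - scores_b
  if (zeroes == "discard") {
    d <- d[d != 0]
    r <- rank(abs(d))
  } else {
    r_all <- rank(abs(d))
    r <- r_all[d != 0]
    d <- d[d != 0]
  }
  m <- length(d)
  if (m == 0) {
    return(structure(list(statistic = 0, n_nonzero = 0L, method = "degenerate",
                          p_value = 1), class = "wilcoxon_paired"))
  }
  w <- sum(r[d > 0])
  use_exact <- method == "exact" || (method == "auto" && m <= exact_max)
  p <- if (use_exact) wilcoxon_exact_p(r, w) else wilcoxon_normal_p(r, w)
  structure(
    list(statistic = w, n_nonzero = m,
         method = if (use_exact) "exact" else "normal", p_value = p),
    class = "wilcoxon_paired"
  )
}

# Exact two-sided p over the 2^m equiprobable sign assignments, computed as
# a convolution over doubled ranks (average ranks double to integers).
wilcoxon_exact_p <- function(ranks, w) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1)  # counts of achievable doubled statistics, offset 1
  f[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), f[seq_len(total + 1 - r)])
    f <- f + shifted
  }
  f <- f / sum(f)
  w2 <- as.integer(round(2 * w))
  lower <- sum(f[seq_len(w2 + 1)])
  upper <- sum(f[(w2 + 1):(total + 1)])
  min(1, 2 * min(lower, upper))
}

# Normal approximation: W+ is a sum of independent r_i * Bernoulli(1/2), so
# E = sum(r)/2 and Var = sum(r^2)/4 (automatically tie-corrected); a 0.5
# continuity correction shrinks |W - E|.
wilcoxon_normal_p <- function(ranks, w) {
  mu <- sum(ranks) / 2
  sg <- sqrt(sum(ranks^2) / 4)
  if (sg == 0) return(1)
  z <- (w - mu - 0.5 * sign(w - mu)) / sg
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' @export
print.wilcoxon_paired <- function(x, ...) {
  cat("Paired Wilcoxon signed-rank:", "W+ =", x$statistic,
      "on", x$n_nonzero, "nonzero pairs,", x$method,
      "p =", format.pval(x$p_value, digits = 3), "\n")
  invisible(x)
}
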