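#' Two-tailed Wilcoxon signed-rank test
#'
#' Paired nonparametric test on the signed ranks of the differences
#' `a - b`. Zero differences are dropped; tied absolute differences receive
#' mid-ranks. For m <= `exact_limit` nonzero differences the p-value is
#' exact: the null distribution of the positive-rank sum W+ over all 2^m
#' equiprobable sign assignments is built by dynamic programming
#' (equivalent to full enumeration), and the two-tailed p-value is the
#' probability of a rank sum at least as far from the null mean as the
#' observed one. For larger m a normal approximation with tie correction
#' and continuity correction is used. When every difference is zero the
#' p-value is 1 by convention.
#'
#' @param a,b Equal-length numeric vectors of paired observations.
#' @param exact_limit Largest m for which the exact distribution is
#'   enumerated (default 20).
#' @return A list with `p_value` (in (0, 1]), `statistic` (W+),
#'   `n_nonzero`, and `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(a, b, exact_limit = 20L) {
  if (length(a) != length(b) || length(a) < 1) {
    abort("`a` and `b` must be equal-length and non-empty.")
  }
  d <- a - b
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(list(p_value = 1, statistic = 0, n_nonzero = 0L, method = "exact"))
  }
  r <- rank(abs(d))                       # mid-ranks for ties
  w_plus <- sum(r[d > 0])
  if (m <= exact_limit) {
    # doubled ranks are integers even with mid-ranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1L)              # f[w+1] = #subsets with rank sum w
    f[1] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), f[seq_len(total + 1L - ri)])
      f <- f + shifted
    }
    mean2 <- total / 2
    dev <- abs(round(2 * w_plus) - mean2)
    w <- 0:total
    p <- sum(f[abs(w - mean2) >= dev - 1e-9]) / 2^m
    method <- "exact"
  } else {
    ties <- table(r)
    mu <- m * (m + 1) / 4
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (w_plus - mu - 0.5 * sign(w_plus - mu)) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(p_value = p, statistic = w_plus, n_nonzero = m, method = method)
}
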