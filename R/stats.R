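# Rank-based statistics used to compare measurements across X-ray energy
# levels: per-target medians over repeat scans, a tie-corrected Friedman
# test implemented from ranks, and an exact Wilcoxon signed-rank test
# against a fixed reference value.

#' Per-target medians over repeated scans
#'
#' @param measurements numeric matrix or data frame, scans in rows, targets in
#'   columns. Even scan counts use the midpoint of the central pair.
#' @return named numeric vector of per-target medians.
#' @export
median_over_scans <- function(measurements) {
  m <- as.matrix(measurements)
  if (length(m) == 0 || nrow(m) < 1) stopf("empty measurement table")
  if (!is.numeric(m)) stopf("measurements must be numeric")
  apply(m, 2, stats::median)
}

#' Friedman rank test across treatments within blocks
#'
#' Ranks are assigned within each block (midranks for ties); the tie-corrected
#' chi-square statistic is
#' `(k-1) * sum_j (R_j - n(k+1)/2)^2 / (A - C)` with `A` the sum of squared
#' ranks and `C = n k (k+1)^2 / 4`, referred to a chi-square distribution with
#' `k - 1` degrees of freedom. When every block is constant (zero rank
#' variance) the statistic is 0 and p = 1.
#'
#' @param mat numeric matrix, blocks (subjects/targets) in rows, treatments
#'   (energy levels) in columns; at least 2 of each, no missing cells.
#' @return list with `statistic`, `df`, `p_value`, `n_blocks`, `n_treatments`.
#' @export
friedman_test <- function(mat) {
  m <- as.matrix(mat)
  if (anyNA(m)) stopf("matrix has missing cells")
  n <- nrow(m); k <- ncol(m)
  if (n < 2 || k < 2) stopf("need at least 2 blocks and 2 treatments")
  r <- t(apply(m, 1, rank))
  Rj <- colSums(r)
  A <- sum(r^2)
  C <- n * k * (k + 1)^2 / 4
  S <- sum((Rj - n * (k + 1) / 2)^2)
  if (A - C <= 0) {
    stat <- 0; p <- 1
  } else {
    stat <- (k - 1) * S / (A - C)
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
  }
  list(statistic = stat, df = k - 1, p_value = p,
       n_blocks = n, n_treatments = k)
}

# exact distribution of the positive-rank sum for given |d| midranks:
# generating-function convolution over doubled ranks (integers even with
# midrank ties). Returns P(W <= w) and P(W >= w).
signed_rank_exact_tails <- function(ranks, W) {
  r2 <- as.integer(round(2 * ranks))
  total <- sum(r2)
  f <- numeric(total + 1L)      # f[s+1] = #assignments with doubled sum s
  f[1L] <- 1
  for (r in r2) {
    g <- f
    g[(r + 1L):(total + 1L)] <- g[(r + 1L):(total + 1L)] + f[1L:(total + 1L - r)]
    f <- g
  }
  f <- f / 2^length(r2)
  w2 <- round(2 * W)
  le <- sum(f[seq_len(min(total, floor(w2 + 1e-9)) + 1L)])
  ge <- sum(f[(max(0, ceiling(w2 - 1e-9)) + 1L):(total + 1L)])
  c(le = le, ge = ge)
}

#' Wilcoxon signed-rank test against a reference value
#'
#' Differences from `reference` are ranked by absolute value (midranks for
#' ties, zero differences dropped); the statistic is the positive-rank sum.
#' The null distribution is exact (full convolution over sign assignments,
#' valid under ties) for `n <= exact_max_n`; larger samples use the normal
#' approximation with tie correction and continuity correction. Two-sided.
#'
#' @param values numeric sample (e.g. per-scene diameter errors, mm).
#' @param reference reference value compared against (default 0.04).
#' @param exact_max_n largest n for the exact distribution (default 25).
#' @return list with `statistic` (positive-rank sum V), `p_value`, `n`
#'   (nonzero differences), `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_vs_reference <- function(values, reference = 0.04, exact_max_n = 25L) {
  d <- values - reference
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stopf("all differences from the reference are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max_n) {
    tails <- signed_rank_exact_tails(r, V)
    p <- min(1, 2 * min(tails["le"], tails["ge"]))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - 0.5 * sign(V - mu)) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = V, p_value = unname(p), n = n, method = method)
}
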