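# Wilcoxon tests with exact small-sample null distributions.
#
# The exact nulls are computed by dynamic programming over the generating
# polynomial of the rank sums (in half-rank units, so midranks from ties are
# handled exactly), which is equivalent to full enumeration of all sign
# patterns / group assignments but runs in polynomial time. Larger samples
# fall back to the normal approximation with tie correction and continuity
# correction.

#' Wilcoxon signed-rank test with an exact (tie-aware) small-sample null
#'
#' Paired test on `x - y` (or on `x` directly when `y` is `NULL`). Zero
#' differences are dropped; with no informative pairs the p-value is 1.
#' For `n <= exactLimit` informative pairs the null distribution of the
#' positive-rank sum is computed exactly over all `2^n` sign patterns
#' (including midranks from tied absolute differences); beyond that, a
#' normal approximation with continuity correction is used.
#'
#' @param x,y paired observations, or differences in `x` with `y = NULL`
#' @param alternative `"two.sided"`, `"greater"` (x tends above y) or
#'   `"less"`
#' @param exactLimit largest n for the exact null (default 25)
#' @return an object of class `"htest"` with the statistic V (positive-rank
#'   sum), p-value, and whether the exact null was used
#' @export
signedRankTest <- function(x, y = NULL,
                           alternative = c("two.sided", "greater", "less"),
                           exactLimit = 25L) {
  alternative <- match.arg(alternative)
  d <- if (is.null(y)) x else x - y
  d <- d[d != 0]
  n <- length(d)
  method <- "Wilcoxon signed-rank test"
  if (n == 0L) {
    res <- list(statistic = c(V = 0), p.value = 1,
                alternative = alternative,
                method = paste(method, "(no informative pairs)"),
                data.name = "paired differences")
    class(res) <- "htest"
    return(res)
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  r2 <- as.integer(round(2 * r))  # half-rank units keep midranks exact
  exact <- n <= exactLimit
  if (exact) {
    # counts over the 2^n sign patterns of the positive-rank sum (DP)
    total <- sum(r2)
    cf <- numeric(total + 1L)
    cf[1L] <- 1
    for (ri in r2) {
      shifted <- c(numeric(ri), cf[seq_len(total + 1L - ri)])
      cf <- cf + shifted
    }
    probs <- cf / 2^n
    v2 <- as.integer(round(2 * v))
    pGreater <- sum(probs[(v2 + 1L):(total + 1L)])
    pLess <- sum(probs[seq_len(v2 + 1L)])
    p <- switch(alternative,
                greater = pGreater,
                less = pLess,
                two.sided = min(1, 2 * min(pGreater, pLess)))
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- v - mu
    cc <- 0.5
    p <- switch(alternative,
                greater = pnorm((z - cc) / sqrt(sig2), lower.tail = FALSE),
                less = pnorm((z + cc) / sqrt(sig2)),
                two.sided = 2 * pnorm((abs(z) - cc) / sqrt(sig2),
                                      lower.tail = FALSE))
    p <- min(1, p)
  }
  res <- list(statistic = c(V = v), p.value = p, alternative = alternative,
              method = paste0(method, if (exact) " (exact)" else
                " (normal approximation)"),
              data.name = "paired differences", exact = exact, n = n)
  class(res) <- "htest"
  res
}

#' Wilcoxon rank-sum test with an exact (tie-aware) small-sample null
#'
#' Two-sample test of `x` versus `y`. For `length(x) + length(y) <=
#' exactLimit` the null distribution of the rank sum of `x` is computed
#' exactly over all group assignments (midranks handled exactly); beyond
#' that, a normal approximation with tie and continuity corrections is
#' used.
#'
#' @param x,y numeric samples
#' @param alternative `"two.sided"`, `"greater"` (x tends above y) or
#'   `"less"`
#' @param exactLimit largest combined n for the exact null (default 30)
#' @return an object of class `"htest"` with the statistic W (Mann-Whitney
#'   U for `x`) and p-value
#' @export
rankSumTest <- function(x, y,
                        alternative = c("two.sided", "greater", "less"),
                        exactLimit = 30L) {
  alternative <- match.arg(alternative)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  stopifnot(n1 >= 1L, n2 >= 1L)
  r <- rank(c(x, y))
  wx <- sum(r[seq_len(n1)])
  u <- wx - n1 * (n1 + 1) / 2
  r2 <- as.integer(round(2 * r))
  exact <- n <= exactLimit
  if (exact) {
    total <- sum(r2)
    # f[k+1, s+1]: number of k-subsets with half-rank sum s
    f <- matrix(0, nrow = n1 + 1L, ncol = total + 1L)
    f[1L, 1L] <- 1
    for (ri in r2) {
      # descending k so each item is used at most once (knapsack update)
      for (k in seq(n1, 1L)) {
        idx <- (ri + 1L):(total + 1L)
        f[k + 1L, idx] <- f[k + 1L, idx] + f[k, idx - ri]
      }
    }
    counts <- f[n1 + 1L, ]
    totalComb <- choose(n, n1)
    w2 <- as.integer(round(2 * wx))
    pGreater <- sum(counts[(w2 + 1L):(total + 1L)]) / totalComb
    pLess <- sum(counts[seq_len(w2 + 1L)]) / totalComb
    p <- switch(alternative,
                greater = pGreater,
                less = pLess,
                two.sided = min(1, 2 * min(pGreater, pLess)))
  } else {
    mu <- n1 * (n + 1) / 2
    ties <- table(r)
    sig2 <- n1 * n2 / 12 *
      ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    z <- wx - mu
    cc <- 0.5
    p <- switch(alternative,
                greater = pnorm((z - cc) / sqrt(sig2), lower.tail = FALSE),
                less = pnorm((z + cc) / sqrt(sig2)),
                two.sided = 2 * pnorm((abs(z) - cc) / sqrt(sig2),
                                      lower.tail = FALSE))
    p <- min(1, p)
  }
  res <- list(statistic = c(W = u), p.value = p, alternative = alternative,
              method = paste0("Wilcoxon rank-sum test",
                              if (exact) " (exact)" else
                                " (normal approximation)"),
              data.name = "x vs y", exact = exact)
  class(res) <- "htest"
  res
}
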