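# Exact nonparametric tests: tie-aware Mann-Whitney via rank-sum counting,
# and the probability-mass two-sided Fisher exact test.

# Count k-subsets of the (integer) scaled mid-ranks by rank sum, via the
# classic subset-sum dynamic programme. Equivalent to full enumeration of
# all choose(n, k) group labelings, including under ties.
.ranksum_counts <- function(scaled_ranks, k) {
  n <- length(scaled_ranks)
  smax <- sum(sort(scaled_ranks, decreasing = TRUE)[seq_len(k)])
  # f[j, s+1] = number of j-subsets with scaled rank sum s
  f <- matrix(0, nrow = k + 1, ncol = smax + 1)
  f[1, 1] <- 1
  for (r in scaled_ranks) {
    jmax <- min(k, n)  # rows updated high-to-low so each item used once
    for (j in seq(jmax, 1)) {
      cols <- seq_len(smax + 1 - r)
      f[j + 1, cols + r] <- f[j + 1, cols + r] + f[j, cols]
    }
  }
  f[k + 1, ]
}

#' Two-tailed Mann-Whitney (Wilcoxon rank-sum) test
#'
#' Ties are handled with mid-ranks. When the number of group labelings
#' `choose(n1 + n2, n1)` does not exceed `exact_limit`, the exact
#' permutation null of the U statistic (including ties) is computed by
#' enumeration and the two-tailed p-value is the null probability of a U at
#' least as far from its mean `n1 n2 / 2` as observed. Otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples (both non-empty).
#' @param exact_limit Maximum number of arrangements for exact enumeration
#'   (default 1e6).
#' @return List of class `germscreen_test`: `statistic` (U for `x`),
#'   `p_value`, `method` (`"exact"` or `"normal_approx"`), `n1`, `n2`.
#' @export
mann_whitney_two_tailed <- function(x, y, exact_limit = 1e6) {
  if (length(x) == 0 || length(y) == 0) stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)])
  u <- w - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (choose(n, n1) <= exact_limit) {
    sr <- as.integer(round(2 * r))  # mid-ranks are multiples of 1/2
    counts <- .ranksum_counts(sr, n1)
    sums <- seq_along(counts) - 1
    us <- (sums - n1 * (n1 + 1)) / 2  # scaled rank sum -> U
    total <- sum(counts)
    extreme <- abs(us - mu) >= abs(u - mu) - 1e-9
    p <- sum(counts[extreme]) / total
    method <- "exact"
  } else {
    ties <- table(r)
    sigma2 <- (n1 * n2 / 12) * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal_approx"
  }
  structure(list(statistic = u, p_value = p, method = method,
                 n1 = n1, n2 = n2),
            class = "germscreen_test")
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Probability-mass method: with both margins fixed, the p-value is the sum
#' of hypergeometric probabilities of every table whose probability does not
#' exceed that of the observed table (with `1e-7` relative slack for
#' floating-point ties).
#'
#' @param a,b,c,d Non-negative integer cell counts, row-wise
#'   (`matrix(c(a, c, b, d), 2)` orientation: `a`,`b` first row).
#' @return List of class `germscreen_test`: `statistic` (the observed
#'   table's hypergeometric probability), `p_value`, `method = "exact"`,
#'   and the table margins.
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cell counts must be non-negative integers")
  }
  m1 <- a + b; m2 <- c + d; k <- a + c
  support <- max(0, k - m2):min(k, m1)
  probs <- stats::dhyper(support, m1, m2, k)
  p_obs <- probs[support == a]
  p <- min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  structure(list(statistic = p_obs, p_value = p, method = "exact",
                 margins = list(row = c(m1, m2), col = c(k, b + d))),
            class = "germscreen_test")
}

#' @export
print.germscreen_test <- function(x, ...) {
  cat(sprintf("statistic = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p_value, x$method))
  invisible(x)
}

# significance stars at the conventional reporting thresholds
.stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}
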