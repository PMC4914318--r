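#' Two-sided Wilcoxon rank-sum test
#'
#' Rank-sum test for a location difference between two independent samples.
#' When both groups are small (largest group size at most \code{exact_max_n})
#' and the pooled data contain no ties, the p-value is exact: the null
#' distribution of the rank sum is built over all
#' \eqn{\choose{n_1+n_2}{n_1}} rank assignments. Otherwise the normal
#' approximation is used, with tie-corrected variance and a 0.5 continuity
#' correction.
#'
#' @param x,y Numeric vectors, each of length at least 1.
#' @param exact_max_n Largest group size for which the exact null
#'   distribution is used (default 10). Ties always force the approximation.
#' @return Two-sided p-value in (0, 1]. Degenerate data (all values
#'   identical) give p = 1.
#' @examples
#' rank_sum_test(c(1, 2), c(3, 4))   # exact: 2 / choose(4, 2)
#' @export
rank_sum_test <- function(x, y, exact_max_n = 10) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("both groups must be non-empty")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) return(1)
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  r <- rank(pooled)
  w <- sum(r[seq_len(n1)])
  ties <- any(duplicated(pooled))
  if (!ties && max(n1, n2) <= exact_max_n) {
    dist <- ranksum_null_counts(n1, n)
    total <- choose(n, n1)
    lo <- sum(dist$count[dist$sum <= w]) / total
    hi <- sum(dist$count[dist$sum >= w]) / total
    return(min(1, 2 * min(lo, hi)))
  }
  mu <- n1 * (n + 1) / 2
  tab <- table(pooled)
  tie_term <- sum(tab^3 - tab)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(1)
  z <- max(0, abs(w - mu) - 0.5) / sqrt(v)
  min(1, 2 * stats::pnorm(-z))
}

# Null distribution of the rank sum of a sample of size n1 drawn from ranks
# 1..n: counts of subsets of each possible sum, by dynamic programming.
ranksum_null_counts <- function(n1, n) {
  smax <- sum((n - n1 + 1):n)
  # f[j+1, s+1] = number of j-subsets of {1..k} with sum s, built up over k
  f <- matrix(0, nrow = n1 + 1L, ncol = smax + 1L)
  f[1L, 1L] <- 1
  for (k in seq_len(n)) {
    for (j in min(k, n1):1L) {
      smin_j <- sum(seq_len(j - 1L))
      reach <- smin_j + k   # smallest new sum when adding rank k
      idx <- (reach + 1L):(smax + 1L)
      f[j + 1L, idx] <- f[j + 1L, idx] + f[j, idx - k]
    }
  }
  sums <- 0:smax
  keep <- f[n1 + 1L, ] > 0
  list(sum = sums[keep], count = f[n1 + 1L, keep])
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusts p-values by the BH step-up procedure: after sorting ascending,
#' \eqn{q_i = p_i m / i}, enforcing monotonicity from the largest rank down
#' and capping at 1; results are returned in the input order.
#'
#' @param p Numeric vector of p-values, all in [0, 1].
#' @return Adjusted values in input order.
#' @export
bh_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0L) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

#' One-sided Fisher's exact test (enrichment)
#'
#' Upper-tail hypergeometric probability \eqn{P(X \ge a)} for the 2x2 table
#' \code{(a, b, c, d)} with all margins fixed, i.e. the one-sided Fisher
#' exact p-value for over-representation of the label inside the cluster.
#'
#' @param a In-cluster with label.
#' @param b In-cluster without label.
#' @param c Out-of-cluster with label.
#' @param d Out-of-cluster without label.
#' @return One-sided p-value in (0, 1].
#' @export
fisher_one_sided <- function(a, b, c, d) {
  counts <- c(a, b, c, d)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts)))
    stop("table entries must be non-negative integers")
  # draw a+b samples from a+c labelled and b+d unlabelled; observe X = a
  hi <- min(a + b, a + c)
  if (a > hi) stop("invalid table")
  sum(stats::dhyper(a:hi, a + c, b + d, a + b))
}

#' Kruskal-Wallis rank test across strata
#'
#' Midrank-based H statistic with tie correction; the p-value comes from the
#' chi-square distribution with (k - 1) degrees of freedom.
#'
#' @param values Numeric vector of observations.
#' @param strata Stratum label per observation (coerced to factor); at least
#'   two non-empty strata are required.
#' @return List with \code{H}, \code{df} and \code{p}.
#' @export
kruskal_wallis <- function(values, strata) {
  values <- as.numeric(values)
  strata <- as.factor(as.character(strata))
  if (length(values) != length(strata))
    stop("values and strata lengths differ")
  counts <- table(strata)
  if (length(counts) < 2L) stop("need at least two strata")
  if (any(counts == 0L)) stop("empty stratum: ", names(counts)[counts == 0L][1L])
  n <- length(values)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = length(counts) - 1L, p = 1))
  r <- rank(values)
  rbar <- tapply(r, strata, mean)
  h <- 12 / (n * (n + 1)) * sum(counts * (rbar - (n + 1) / 2)^2)
  tab <- table(values)
  corr <- 1 - sum(tab^3 - tab) / (n^3 - n)
  h <- h / corr
  df <- length(counts) - 1L
  list(H = h, df = df, p = stats::pchisq(h, df, lower.tail = FALSE))
}
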