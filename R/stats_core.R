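#' Pearson chi-squared test on 2x2 contingency tables
#'
#' Vectorised, uncorrected Pearson chi-squared test on one or more 2x2
#' tables of read counts. Row 1 is the control group (methylated,
#' unmethylated), row 2 the exposed group. This is the window-level test
#' behind the DMR caller.
#'
#' @param a,b,c,d Non-negative integer counts: `a`,`b` are the control
#'   methylated/unmethylated counts, `c`,`d` the exposed counts. All four
#'   must have equal length. Alternatively `a` may be a single 2x2 matrix
#'   `rbind(c(a,b), c(c,d))` and `b`,`c`,`d` omitted.
#' @param correct Apply the Yates continuity correction. Default `FALSE`:
#'   the conventional reading of "chi-squared test" in sliding-window DMR
#'   callers is the uncorrected Pearson statistic.
#'
#' @return A list with numeric vectors `statistic` and `p`. Tables with a
#'   zero marginal (an all-zero row or column) have an undefined test and
#'   return `NA` in both fields; callers are expected to skip them.
#'
#' @examples
#' chi2_2x2(30, 10, 10, 30)           # statistic 20, p ~ 7.7e-6
#' chi2_2x2(matrix(c(20, 20, 20, 20), 2, byrow = TRUE))  # statistic 0
#' @export
chi2_2x2 <- function(a, b = NULL, c = NULL, d = NULL, correct = FALSE) {
  if (is.matrix(a)) {
    stopifnot(identical(dim(a), c(2L, 2L)), is.null(b))
    m <- a
    a <- m[1, 1]; b <- m[1, 2]; c <- m[2, 1]; d <- m[2, 2]
  }
  n <- length(a)
  stopifnot(length(b) == n, length(c) == n, length(d) == n)
  if (any(c(a, b, c, d) < 0, na.rm = TRUE)) {
    stop("counts must be non-negative")
  }
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  r1 <- a + b; r2 <- c + d
  c1 <- a + c; c2 <- b + d
  tot <- r1 + r2
  ok <- r1 > 0 & r2 > 0 & c1 > 0 & c2 > 0
  stat <- rep(NA_real_, n)
  # |ad - bc| form of the Pearson statistic; algebraically identical to
  # sum((O-E)^2/E) but avoids forming the four expected counts
  num <- abs(a * d - b * c)
  if (correct) num <- pmax(0, num - tot / 2)
  stat[ok] <- (tot[ok] * num[ok]^2) / (r1[ok] * r2[ok] * c1[ok] * c2[ok])
  p <- rep(NA_real_, n)
  p[ok] <- chi2_sf_df1(stat[ok])
  list(statistic = stat, p = p)
}

#' Upper tail of the chi-squared distribution with 1 degree of freedom
#'
#' Survival function backing [chi2_2x2()]. Equal to
#' `erfc(sqrt(x/2))`.
#'
#' @param x Non-negative numeric vector of statistic values.
#' @return `P(X >= x)` for `X ~ chisq(df = 1)`.
#' @export
chi2_sf_df1 <- function(x) {
  if (any(x < 0, na.rm = TRUE)) stop("x must be >= 0")
  stats::pchisq(x, df = 1, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment, returned in the input order. `NA` p-values are
#' left `NA` and do not count towards the number of tests.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order as `p`,
#'   satisfying `q >= p` elementwise.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Hypergeometric upper-tail probability
#'
#' `P(X >= s)` where `X` counts the successes in `n` draws without
#' replacement from a universe of `N` items of which `K` are successes.
#' Used for the cross-tissue set-sharing enrichment test.
#'
#' @param N Universe size.
#' @param K Number of successes in the universe (e.g. liver-significant
#'   features).
#' @param n Number of draws (e.g. blood-significant features).
#' @param s Observed shared count.
#' @return The exact tail probability, computed in log space by
#'   `stats::phyper`.
#' @examples
#' hypergeom_tail(10, 5, 5, 5)  # 1/252
#' @export
hypergeom_tail <- function(N, K, n, s) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(s) == 1)
  if (K < 0 || K > N || n < 0 || n > N || s < 0 || s > min(K, n)) {
    stop("inconsistent hypergeometric arguments: need 0 <= K <= N, ",
         "0 <= n <= N, 0 <= s <= min(K, n)")
  }
  stats::phyper(s - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Pearson correlation with an explicit undefined signal
#'
#' Sample Pearson correlation between matched effect sizes (for instance
#' female vs male log2 fold changes of shared features). Rather than
#' returning a spurious number, degenerate inputs yield `NA`.
#'
#' @param x,y Numeric vectors of equal length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return The correlation coefficient, or `NA_real_` when fewer than 3
#'   pairs are available or either vector has zero variance.
#' @export
pearson_r <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) return(NA_real_)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}
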