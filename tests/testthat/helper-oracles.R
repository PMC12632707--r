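# Independent brute-force oracles used across the suite. These stay
# deliberately naive and share no code with the implementation.

# Pearson chi-squared statistic straight from sum((O-E)^2 / E)
oracle_chi2_stat <- function(a, b, c, d) {
  obs <- c(a, b, c, d)
  r <- c(a + b, a + b, c + d, c + d)
  cc <- c(a + c, b + d, a + c, b + d)
  expd <- r * cc / sum(obs)
  sum((obs - expd)^2 / expd)
}

# df-1 chi-squared upper tail by numeric integration of the density
oracle_chi2_tail <- function(x) {
  if (x == 0) return(1)
  # substitute t = x + u and pull out exp(-x/2) so the quadrature works
  # on a well-scaled integrand even in the far tail
  f <- function(u) exp(-u / 2) / sqrt(2 * pi * (x + u))
  exp(-x / 2) * stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}

# naive O(m^2) step-up BH from the definition
oracle_bh <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "first")
  q <- numeric(m)
  for (i in seq_len(m)) {
    cand <- p * m / r
    q[i] <- min(1, min(cand[r >= r[i]]))
  }
  q
}

# hypergeometric upper tail by summing exact binomial coefficients
oracle_hyper_tail <- function(N, K, n, s) {
  ks <- s:min(K, n)
  ks <- ks[ks >= max(0, n + K - N)]
  if (length(ks) == 0) return(0)
  sum(choose(K, ks) * choose(N - K, n - ks)) / choose(N, n)
}

# all-pairs interval intersection
oracle_intersect <- function(a, b, min_overlap = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] != b$chrom[j]) next
      ov <- min(a$end[i], b$end[j]) - max(a$start[i], b$start[j])
      if (ov >= min_overlap) {
        out[[length(out) + 1]] <- data.frame(query = i, subject = j,
                                             overlap = ov)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(query = integer(), subject = integer(),
                      overlap = integer()))
  }
  do.call(rbind, out)
}

# random region set on a toy genome
random_regions <- function(n, chroms = c("chr1", "chr2"), max_pos = 1e4,
                           max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.table::data.table(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_len, n, replace = TRUE))
}
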