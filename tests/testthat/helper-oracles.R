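# Independent brute-force oracles the implementation is checked against.

# Naive O(n^2) sample entropy: explicit template matching with the same
# conventions as the implementation (templates i = 1..n-m for both lengths,
# Chebyshev distance <= r, self-matches excluded, A == 0 -> log(B)).
naive_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (abs(x[i + m] - x[j + m]) <= r) A <- A + 1L
      }
    }
  }
  if (B == 0) return(0)
  if (A == 0) return(log(B))
  log(B) - log(A)
}

# Sort-based quantile features (type-7 linear interpolation, by hand).
sort_quantile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}
sort_iqr <- function(x) sort_quantile(x, 0.75) - sort_quantile(x, 0.25)
sort_median <- function(x) sort_quantile(x, 0.5)
sort_mad <- function(x) sort_median(abs(x - sort_median(x)))

# Classic (tie-free) Friedman statistic straight from the textbook formula.
friedman_hand <- function(m) {
  n <- nrow(m); k <- ncol(m)
  rs <- colSums(t(apply(m, 1, rank)))
  12 / (n * k * (k + 1)) * sum(rs^2) - 3 * n * (k + 1)
}
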