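# Independent brute-force oracles used to check the implementation.

# All-pairs interval overlap counter (>= 1 bp rule).
overlap_oracle <- function(reads, units) {
  vapply(seq_len(nrow(units)), function(i) {
    sum(reads$chrom == units$chrom[i] &
          pmax(reads$start, units$start[i]) < pmin(reads$end, units$end[i]))
  }, numeric(1))
}

# Full 2^n sign enumeration of the signed-rank null (tie-free d assumed).
wilcoxon_enum_oracle <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  p_up <- mean(Ws >= W)
  p_lo <- mean(Ws <= W)
  list(W = W, p = min(1, 2 * min(p_up, p_lo)))
}

# Direct-summation binomial upper tail P(X >= a | n, p).
binom_tail_oracle <- function(a, n, p) {
  if (a <= 0) return(1)
  if (a > n) return(0)
  k <- a:n
  sum(exp(lchoose(n, k) + k * log(p) + (n - k) * log1p(-p)))
}

# Direct-summation Poisson upper tail P(X >= c | lambda).
pois_tail_oracle <- function(c0, lambda) {
  if (c0 <= 0) return(1)
  k <- c0:max(c0 + 200, ceiling(lambda + 40 * sqrt(lambda) + 200))
  sum(exp(k * log(lambda) - lambda - lgamma(k + 1)))
}

# Hand step-up Benjamini-Hochberg.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Kolmogorov distance of a sample from Uniform(0, 1).
ks_uniform <- function(p) {
  p <- sort(p)
  n <- length(p)
  max(abs(p - seq_len(n) / n), abs(p - (seq_len(n) - 1) / n))
}
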