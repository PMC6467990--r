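test_that("sqrt_pearson is exact under proportionality and matches the
           covariance formula", {
  x <- c(0, 1, 4, 9, 16)
  expect_equal(sqrt_pearson(x, x)$r, 1)
  expect_equal(sqrt_pearson(x, 3.7 * x)$r, 1)
  set.seed(8)
  a <- runif(10, 0, 50); b <- runif(10, 0, 50)
  sa <- sqrt(a); sb <- sqrt(b)
  r_hand <- sum((sa - mean(sa)) * (sb - mean(sb))) /
    sqrt(sum((sa - mean(sa))^2) * sum((sb - mean(sb))^2))
  expect_equal(sqrt_pearson(a, b)$r, r_hand, tolerance = 1e-12)
  expect_error(sqrt_pearson(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("paired count test matches binomial-tail and normal-CDF oracles", {
  # symmetric null: a = b with equal libraries
  # (the one-sided tail includes the observed atom, so Z sits just below 0
  # rather than at it; the null assertion is on p)
  res <- paired_count_test(c(5, 9), c(5, 9), c(1e6, 1e6), c(1e6, 1e6))
  expect_true(res$p_value > 0.5)
  # one replicate, 8 vs 2, equal libraries: upper tail = 56/1024
  res1 <- paired_count_test(8, 2, 1e6, 1e6)
  expect_equal(res1$p_k, 56 / 1024, tolerance = 1e-12)
  expect_equal(res1$p_k, binom_tail_oracle(8, 10, 0.5), tolerance = 1e-12)
  # two identical replicates: Z = sqrt(2) * qnorm(1 - 56/1024), two-sided p
  # checked against an erf-based normal CDF evaluated independently
  res2 <- paired_count_test(c(8, 8), c(2, 2), c(1e6, 1e6), c(1e6, 1e6))
  Z <- sqrt(2) * qnorm(1 - 56 / 1024)
  expect_equal(res2$statistic, Z, tolerance = 1e-10)
  expect_equal(res2$p_value, pracma::erfc(abs(Z) / sqrt(2)),
               tolerance = 1e-10)
  expect_equal(res2$direction, "up")
  # unequal libraries shift the null proportion
  res3 <- paired_count_test(8, 2, 4e6, 1e6)
  expect_equal(res3$p_k, binom_tail_oracle(8, 10, 0.8), tolerance = 1e-12)
  # empty replicates are uninformative
  res0 <- paired_count_test(c(0, 0), c(0, 0), c(1e6, 1e6), c(1e6, 1e6))
  expect_equal(res0$p_value, 1)
  expect_equal(res0$direction, "none")
})

test_that("paired count test p-values are near-uniform under a binomial null", {
  set.seed(31)
  G <- 4000L
  n_k <- matrix(rpois(G * 2, 120), G)
  a <- matrix(rbinom(G * 2, as.vector(n_k), 0.5), G)
  b <- n_k - a
  res <- primedchip:::paired_count_test_all(a, b, c(1e6, 1e6), c(1e6, 1e6))
  expect_lt(ks_uniform(res$p_value), 0.05)
})

test_that("Wilcoxon signed-rank matches its spec'd exact examples", {
  expect_equal(wilcoxon_signed_rank(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  r1 <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(r1$statistic, 6)
  expect_equal(r1$p_value, 0.25)
  r2 <- wilcoxon_signed_rank(c(1, -2, 3))
  expect_equal(r2$statistic, 4)
  expect_equal(r2$p_value, 0.75)
})

test_that("exact Wilcoxon equals full sign enumeration and wilcox.test", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(2:10, 1)
    d <- round(runif(n, -5, 5), 3)
    d <- d[d != 0]
    if (length(d) < 2 || anyDuplicated(abs(d))) next
    res <- wilcoxon_signed_rank(d)
    ora <- wilcoxon_enum_oracle(d)
    expect_equal(res$statistic, ora$W)
    expect_equal(res$p_value, ora$p, tolerance = 1e-12)
    ref <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
    expect_equal(res$p_value, unname(ref$p.value), tolerance = 1e-12)
  }
})

test_that("normal approximation is close to exact for n in 20..25", {
  set.seed(29)
  for (i in 1:10) {
    n <- sample(20:25, 1)
    d <- runif(n, -3, 3)                    # continuous, tie-free
    # exact reference from the signed-rank distribution (enumeration is
    # infeasible at 2^25; psignrank tabulates the same null exactly)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    p_exact <- min(1, 2 * min(psignrank(W - 1, n, lower.tail = FALSE),
                              psignrank(W, n)))
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (W - mu - sign(W - mu) * 0.5) / sigma
    p_norm <- 2 * pnorm(-abs(z))
    expect_lt(abs(p_norm - p_exact), 0.02)
    # and the implementation takes the exact path here
    expect_equal(wilcoxon_signed_rank(d)$p_value, p_exact, tolerance = 1e-12)
  }
})

test_that("small tied samples are enumerated exactly, large ones approximated", {
  # 5 equal differences: all-positive sign pattern, exact p = 2/32
  res5 <- wilcoxon_signed_rank(rep(1, 5))
  expect_equal(res5$method, "exact")
  expect_equal(res5$p_value, 2 / 32)
  # tied n = 10: enumeration oracle over midranks
  d <- c(1, 1, -1, 2, 2, 3, -3, 4, 4, 5)
  res <- wilcoxon_signed_rank(d)
  expect_equal(res$method, "exact")
  ora <- wilcoxon_enum_oracle(d)
  expect_equal(res$p_value, ora$p, tolerance = 1e-12)
  # tied n > 15 routes to the tie-corrected normal approximation
  d20 <- rep(c(1, 2, -2, 3, 4), 4)
  res20 <- wilcoxon_signed_rank(d20)
  expect_equal(res20$method, "normal")
  ref <- suppressWarnings(stats::wilcox.test(d20, correct = TRUE))
  expect_equal(res20$p_value, unname(ref$p.value), tolerance = 1e-10)
})

test_that("BH adjustment equals the hand step-up formula", {
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(41)
  for (i in 1:10) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # step-up monotonicity: lowering one p never raises any q
  p <- runif(20)
  q0 <- bh_adjust(p)
  p2 <- p; p2[7] <- p2[7] / 10
  expect_true(all(bh_adjust(p2) <= q0 + 1e-12))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})
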