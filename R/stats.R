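# Statistical primitives: square-root Pearson correlation, the paired
# binomial-Stouffer count test, exact/approximate Wilcoxon signed-rank, and
# Benjamini-Hochberg adjustment.

#' Pearson correlation on square-root-transformed values
#'
#' The genotype-vs-genotype ChIP scatters are drawn and correlated on the
#' square root of RPM, which stabilises the variance of count-derived signal.
#'
#' @param x,y non-negative numeric vectors of equal length >= 3 (RPM values).
#' @return list with `r`, `n`, `transform = "sqrtRPM"`.
#' @export
sqrt_pearson <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (any(x < 0) || any(y < 0)) stop("sqrt_pearson requires non-negative input")
  sx <- sqrt(x); sy <- sqrt(y)
  if (stats::sd(sx) == 0 || stats::sd(sy) == 0) {
    stop("zero variance after square-root transform")
  }
  list(r = stats::cor(sx, sy), n = length(x), transform = "sqrtRPM")
}

#' Paired count test (binomial per replicate, Stouffer-combined)
#'
#' For each replicate pair k, conditional on the total n_k = a_k + b_k, the
#' count a_k is binomial with null proportion pi_k = A_k / (A_k + B_k) given
#' by the two library sizes. The one-sided upper binomial p-value
#' P(X >= a_k | n_k, pi_k) is mapped to a signed normal score
#' z_k = qnorm(1 - p_k) (clamped to [-8, 8] against floating-point
#' under/overflow), the scores are Stouffer-combined Z = sum(z_k) / sqrt(K),
#' and the two-sided p is 2 * pnorm(-|Z|). Replicates with n_k = 0 carry no
#' information and are dropped from the combination; if all are empty the
#' result is p = 1 with direction "none".
#'
#' The effect is the fold change of pseudocounted replicate-mean RPM (a over
#' b, half-minimum pseudocount over the pooled RPM values).
#'
#' @param a_counts,b_counts integer vectors, one entry per replicate pair.
#' @param a_libsizes,b_libsizes library sizes (> 0), same length.
#' @return list with `statistic` (Z), `p_value`, `effect`, `direction`
#'   (`"up"`, `"down"`, `"none"`), and per-replicate `z_k`, `pi_k`, `p_k`.
#' @export
paired_count_test <- function(a_counts, b_counts, a_libsizes, b_libsizes) {
  K <- length(a_counts)
  stopifnot(K >= 1L, length(b_counts) == K,
            length(a_libsizes) == K, length(b_libsizes) == K)
  if (any(a_libsizes <= 0) || any(b_libsizes <= 0)) stop("library sizes must be > 0")
  a <- matrix(a_counts, nrow = 1L); b <- matrix(b_counts, nrow = 1L)
  res <- paired_count_test_all(a, b, a_libsizes, b_libsizes)
  n_k <- a_counts + b_counts
  pi_k <- a_libsizes / (a_libsizes + b_libsizes)
  p_k <- stats::pbinom(a_counts - 1L, n_k, pi_k, lower.tail = FALSE)
  z_k <- clamp_z(stats::qnorm(p_k, lower.tail = FALSE))
  z_k[n_k == 0L] <- NA_real_
  list(statistic = res$statistic, p_value = res$p_value,
       effect = res$effect, direction = res$direction,
       z_k = z_k, pi_k = pi_k, p_k = p_k)
}

clamp_z <- function(z) {
  z[z > 8] <- 8
  z[z < -8] <- -8
  z
}

# Vectorized engine: a, b are genes x replicates count matrices.
# Returns a data.frame with one row per gene.
paired_count_test_all <- function(a, b, a_libsizes, b_libsizes) {
  stopifnot(ncol(a) == ncol(b), nrow(a) == nrow(b))
  n <- a + b
  pi0 <- matrix(a_libsizes / (a_libsizes + b_libsizes),
                nrow = nrow(a), ncol = ncol(a), byrow = TRUE)
  p_up <- stats::pbinom(a - 1L, n, pi0, lower.tail = FALSE)
  z <- clamp_z(stats::qnorm(p_up, lower.tail = FALSE))
  z[n == 0L] <- NA_real_
  k_eff <- rowSums(!is.na(z))
  Z <- ifelse(k_eff > 0, rowSums(z, na.rm = TRUE) / sqrt(pmax(k_eff, 1L)), 0)
  p <- ifelse(k_eff > 0, 2 * stats::pnorm(-abs(Z)), 1)
  a_rpm <- rpm(a, a_libsizes); b_rpm <- rpm(b, b_libsizes)
  eff <- rep(NA_real_, nrow(a))
  if (any(cbind(a_rpm, b_rpm) > 0)) {
    pooled <- add_half_min_pseudocount(cbind(a_rpm, b_rpm))
    pc <- attr(pooled, "pseudocount")
    eff <- rowMeans(a_rpm + pc) / rowMeans(b_rpm + pc)
  }
  direction <- ifelse(k_eff == 0 | Z == 0, "none", ifelse(Z > 0, "up", "down"))
  data.frame(gene_id = rownames(a) %||% as.character(seq_len(nrow(a))),
             statistic = Z, p_value = p, effect = eff, direction = direction,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Wilcoxon signed-rank test (exact for small tie-free samples)
#'
#' Differences `d = x - y` (or `x` alone against zero) are computed, zero
#' differences dropped, and the remaining absolute differences midranked;
#' W is the sum of ranks of positive differences. For n <= 25 after zero
#' removal and no ties in |d|, the exact two-sided p-value is
#' `min(1, 2 * min(P(W+ >= w), P(W+ <= w)))` under the exact signed-rank null
#' distribution; with ties but n <= 15 the same two-sided rule is evaluated
#' by direct enumeration of all 2^n sign assignments over the midranks;
#' otherwise a normal approximation with tie-corrected variance and a 0.5
#' continuity correction is used.
#'
#' @param x numeric vector.
#' @param y paired numeric vector, or a scalar (default 0) for the
#'   one-sample test.
#' @return list with `statistic` (W), `p_value`, `effect`
#'   (median difference), `direction`, `n` (pairs after zero removal),
#'   `method` (`"exact"` or `"normal"`).
#' @export
wilcoxon_signed_rank <- function(x, y = 0) {
  if (length(y) == 1L) y <- rep(y, length(x))
  stopifnot(length(x) == length(y), length(x) >= 1L)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(list(statistic = 0, p_value = 1, effect = 0, direction = "none",
                n = 0L, method = "exact"))
  }
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  ties <- anyDuplicated(abs(d)) > 0L
  if (n <= 25L && !ties) {
    p_up <- stats::psignrank(W - 1, n, lower.tail = FALSE)
    p_lo <- stats::psignrank(W, n)
    p <- min(1, 2 * min(p_up, p_lo))
    method <- "exact"
  } else if (n <= 15L) {
    # ties at small n: enumerate all sign assignments over the midranks
    Ws <- 0
    for (ri in r) Ws <- c(Ws, Ws + ri)
    p <- min(1, 2 * min(mean(Ws >= W), mean(Ws <= W)))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(abs(d))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    dev <- W - mu
    z <- if (dev == 0) 0 else (dev - sign(dev) * 0.5) / sqrt(sigma2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal"
  }
  med <- stats::median(d)
  list(statistic = W, p_value = p, effect = med,
       direction = if (med > 0) "up" else if (med < 0) "down" else "none",
       n = n, method = method)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @return q-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (anyNA(p_values) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}
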