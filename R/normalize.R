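# Normalizations: RPM, RPKM, half-minimum pseudocount, log2 ratios, row
# z-scores. Normalized matrices carry `scale` and `pseudocount` attributes.

#' Reads per million mapped reads
#'
#' `value = count * 1e6 / library_size`. For a matrix, `library_size` is
#' recycled per column.
#'
#' @param counts numeric vector or genes x samples matrix.
#' @param library_size per-sample library size(s), > 0.
#' @return same shape as `counts`, attribute `scale = "RPM"`.
#' @export
rpm <- function(counts, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  out <- if (is.matrix(counts)) {
    sweep(counts, 2L, library_size, "/") * 1e6
  } else counts * 1e6 / library_size
  structure(out, scale = "RPM")
}

#' Reads per kilobase per million mapped reads
#'
#' `value = count * 1e9 / (unit_length * library_size)`.
#'
#' @inheritParams rpm
#' @param unit_lengths per-gene unit lengths in bp, > 0.
#' @return same shape as `counts`, attribute `scale = "RPKM"`.
#' @export
rpkm <- function(counts, unit_lengths, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0")
  if (any(unit_lengths <= 0)) stop("unit_lengths must be > 0")
  out <- if (is.matrix(counts)) {
    sweep(counts, 2L, library_size, "/") / unit_lengths * 1e9
  } else counts * 1e9 / (unit_lengths * library_size)
  structure(out, scale = "RPKM")
}

#' Add a half-minimum pseudocount
#'
#' Adds half of the smallest strictly positive value of the whole matrix to
#' every entry (applied before ratio or log computations so zeros never reach
#' a denominator or logarithm). The offset is recorded in the `pseudocount`
#' attribute.
#'
#' @param x numeric matrix or vector with at least one strictly positive value.
#' @return `x + m/2` with attribute `pseudocount = m/2`.
#' @export
add_half_min_pseudocount <- function(x) {
  pos <- x[x > 0]
  if (length(pos) == 0L) stop("all values are zero; pseudocount undefined")
  pc <- min(pos) / 2
  out <- x + pc
  attr(out, "pseudocount") <- pc
  attr(out, "scale") <- attr(x, "scale")
  out
}

#' Per-gene log2 ratio of two conditions
#'
#' Replicate columns are averaged before the ratio is taken; inputs must be
#' strictly positive (pseudocount first, see [add_half_min_pseudocount()]).
#'
#' @param numerator,denominator numeric vectors, or matrices whose columns
#'   are replicates of the respective condition.
#' @return numeric vector of `log2(mean(num) / mean(den))` per gene.
#' @export
log2_ratio <- function(numerator, denominator) {
  num <- if (is.matrix(numerator)) rowMeans(numerator) else as.numeric(numerator)
  den <- if (is.matrix(denominator)) rowMeans(denominator) else as.numeric(denominator)
  if (any(num <= 0) || any(den <= 0)) {
    stop("log2_ratio requires strictly positive values; ",
         "apply add_half_min_pseudocount() first")
  }
  log2(num / den)
}

#' Row z-scores
#'
#' Each row is centred by its mean and divided by its population standard
#' deviation (divisor n); constant rows map to all-zero.
#'
#' @param x numeric matrix with >= 2 columns.
#' @return matrix of z-scores, attribute `scale = "zscore"`.
#' @export
zscore_rows <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  mu <- rowMeans(x)
  sd_pop <- sqrt(rowMeans((x - mu)^2))
  z <- (x - mu) / ifelse(sd_pop == 0, 1, sd_pop)
  z[sd_pop == 0, ] <- 0
  structure(z, scale = "zscore")
}

# Replicate-averaged normalized values for one condition of a count matrix.
cm_mean_norm <- function(cm, genotype, stage, assay, scale = c("RPM", "RPKM")) {
  scale <- match.arg(scale)
  sel <- cm_select(cm, genotype = genotype, stage = stage, assay = assay)
  m <- if (scale == "RPM") {
    rpm(sel$counts, sel$samples$library_size)
  } else {
    rpkm(sel$counts, sel$unit_lengths, sel$samples$library_size)
  }
  rowMeans(m)
}
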