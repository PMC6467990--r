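# Read extension, per-annotation-unit overlap counting, metagene profiles.

#' Extend reads to a fixed fragment length
#'
#' Each read keeps its 5' end fixed and is extended in its 3' direction to
#' exactly `target_length` bp (the average insert size of the sequenced
#' library, 250 bp by default in this workflow). Reads already longer than
#' the target are truncated from their 5' end, so all fragments end up the
#' same length. Coordinates are clamped at 0 and, when `chrom_lengths` is
#' given, at the chromosome end; the operation is idempotent.
#'
#' @param reads data.frame with `chrom`, `start`, `end`, `strand`.
#' @param target_length fragment length in bp (> 0).
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return data.frame of extended reads.
#' @export
extend_reads <- function(reads, target_length = 250L, chrom_lengths = NULL) {
  stopifnot(target_length > 0)
  L <- as.integer(target_length)
  out <- reads
  plus <- reads$strand != "-"
  out$end[plus] <- reads$start[plus] + L
  out$start[!plus] <- pmax(0L, reads$end[!plus] - L)
  if (!is.null(chrom_lengths)) {
    lim <- as.integer(chrom_lengths[out$chrom])
    out$end <- pmin(out$end, lim)
  }
  out
}

#' Count reads overlapping each annotation unit
#'
#' A read contributes 1 to every unit it shares at least one base pair with
#' (multi-assignment); reads are expected to have been extended to fragment
#' length beforehand.
#'
#' @param reads data.frame of (extended) read intervals.
#' @param units data.frame of genic regions (see [genic_regions()]).
#' @return named integer vector of counts, one per unit, named by `gene_id`.
#' @export
count_overlaps <- function(reads, units) {
  if (nrow(reads) == 0L) {
    return(setNames(integer(nrow(units)), units$gene_id))
  }
  n <- GenomicRanges::countOverlaps(as_granges(units), as_granges(reads),
                                    minoverlap = 1L, ignore.strand = TRUE)
  setNames(as.integer(n), units$gene_id)
}

#' Metagene positional profile over gene body plus flanks
#'
#' Per-base coverage is computed over each gene's body plus `flank` bp on
#' each side; the body is rescaled to `body_bins` equal-width bins and each
#' flank to `flank_bins` bins, minus-strand genes are reversed so bin order
#' runs 5' to 3', and bins are averaged across genes. Bodies shorter than
#' `body_bins` are mapped onto the bin grid by per-base linear interpolation.
#'
#' @param reads data.frame of read intervals; pass `fragment_length` to extend
#'   them first, or `NULL` to use them as given.
#' @param genes gene data.frame (bodies; flanks are added here).
#' @param flank flank width in bp.
#' @param body_bins,flank_bins bin counts for body and each flank.
#' @param library_size if non-`NULL`, values are scaled to RPM-per-base
#'   (`* 1e6 / library_size`); otherwise reads-per-base.
#' @param fragment_length optional extension target applied to `reads`.
#' @return object of class `metagene_profile`: list with `values` (numeric,
#'   length `2*flank_bins + body_bins`), `bin_class` (`"up"`, `"body"`,
#'   `"down"`), `body_bins`, `flank_bins`, `n_genes`, `signal_units`.
#' @export
metagene_profile <- function(reads, genes, flank = 2000L, body_bins = 100L,
                             flank_bins = 50L, library_size = NULL,
                             fragment_length = NULL) {
  stopifnot(body_bins >= 1L, flank_bins >= 1L, flank >= 1L)
  if (nrow(genes) == 0L) stop("metagene_profile requires at least one gene")
  if (!is.null(fragment_length)) reads <- extend_reads(reads, fragment_length)
  cov <- IRanges::coverage(as_granges(reads))
  flank <- as.integer(flank)
  nbins <- 2L * flank_bins + body_bins
  acc <- numeric(nbins)
  for (i in seq_len(nrow(genes))) {
    v <- region_coverage(cov, genes$chrom[i],
                         genes$start[i] - flank, genes$end[i] + flank)
    if (genes$strand[i] == "-") v <- rev(v)
    up <- v[seq_len(flank)]
    body <- v[(flank + 1L):(length(v) - flank)]
    down <- v[(length(v) - flank + 1L):length(v)]
    acc <- acc + c(rebin(up, flank_bins), rebin(body, body_bins),
                   rebin(down, flank_bins))
  }
  values <- acc / nrow(genes)
  units <- "reads-per-base"
  if (!is.null(library_size)) {
    stopifnot(library_size > 0)
    values <- values * 1e6 / library_size
    units <- "RPM-per-base"
  }
  structure(
    list(values = values,
         bin_class = rep(c("up", "body", "down"),
                         c(flank_bins, body_bins, flank_bins)),
         body_bins = as.integer(body_bins), flank_bins = as.integer(flank_bins),
         n_genes = nrow(genes), signal_units = units),
    class = "metagene_profile"
  )
}

# Per-base coverage over [start, end) (0-based half-open), zero-padded
# outside the chromosome / for absent chromosomes.
region_coverage <- function(cov, chrom, start, end) {
  len <- end - start
  v <- numeric(len)
  if (!chrom %in% names(cov)) return(v)
  rle <- cov[[chrom]]
  lo <- max(start, 0L)
  hi <- min(end, length(rle))
  if (lo >= hi) return(v)
  seg <- as.numeric(IRanges::Views(rle, start = lo + 1L, end = hi)[[1L]])
  v[(lo - start + 1L):(hi - start)] <- seg
  v
}

# Rescale a per-base vector to n bins: block means when len >= n, linear
# interpolation onto the bin grid otherwise.
rebin <- function(v, n) {
  len <- length(v)
  if (len == n) return(v)
  if (len >= n) {
    bin <- floor((seq_len(len) - 1L) * n / len) + 1L
    return(as.numeric(rowsum(v, bin) / tabulate(bin, n)))
  }
  if (len == 1L) return(rep(v, n))
  stats::approx(seq(0, 1, length.out = len), v,
                xout = seq(0, 1, length.out = n))$y
}

#' Write a metagene profile as TSV
#'
#' Columns: `bin_index`, `bin_class` (up/body/down), `value`.
#' @param profile a `metagene_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  write_atomic(data.frame(bin_index = seq_along(profile$values),
                          bin_class = profile$bin_class,
                          value = profile$values), path)
}
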