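# Windowed Poisson local-lambda enrichment calling for TF ChIP versus a
# control sample, peak merging, and peak-to-gene assignment.

#' Sliding-window Poisson enrichment of treatment over control
#'
#' The genome is tiled with sliding windows (`width`, `step`). Control counts
#' are scaled by the treatment/control library-size ratio, and each window's
#' null expectation is the local lambda: the maximum of (i) the scaled
#' control count in the window, (ii) the scaled control count in a 10 kb span
#' centred on the window, prorated to window width, and (iii) the genome-wide
#' treatment rate times window width. The enrichment p-value is the Poisson
#' upper tail P(X >= treat_count | lambda), BH-adjusted genome-wide.
#'
#' @param treat,control data.frames of extended read intervals.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @param width,step window width and step in bp (`width >= step > 0`).
#' @param treat_lib,control_lib library sizes; default to the number of reads
#'   in each set.
#' @return data.frame of windows: `chrom`, `start`, `end`, `treat_count`,
#'   `control_count`, `lambda_local`, `p_value`, `q_value`.
#' @export
window_enrichment <- function(treat, control, chrom_lengths,
                              width = 500L, step = 250L,
                              treat_lib = NULL, control_lib = NULL) {
  stopifnot(width >= step, step > 0)
  treat_lib <- treat_lib %||% nrow(treat)
  control_lib <- control_lib %||% nrow(control)
  if (control_lib <= 0) stop("control library size must be > 0")
  win <- tile_windows(chrom_lengths, width, step)
  win_gr <- as_granges(win)
  # fragments are assigned to windows by their midpoint, so that window
  # counts, the 10 kb prorated local count and the genome-rate floor all
  # scale identically with span (any-overlap counting would inflate window
  # counts by (width + fragment)/width relative to the prorated floors)
  t_gr <- as_granges(read_midpoints(treat))
  c_gr <- as_granges(read_midpoints(control))
  win$treat_count <- GenomicRanges::countOverlaps(win_gr, t_gr,
                                                  ignore.strand = TRUE)
  win$control_count <- GenomicRanges::countOverlaps(win_gr, c_gr,
                                                    ignore.strand = TRUE)
  span <- 10000L
  centre <- (win$start + win$end) %/% 2L
  local_df <- data.frame(chrom = win$chrom,
                         start = pmax(0L, centre - span %/% 2L),
                         end = centre + span %/% 2L)
  ctrl_local <- GenomicRanges::countOverlaps(as_granges(local_df), c_gr,
                                             ignore.strand = TRUE)
  # (c_gr holds midpoints, so the width/span proration below is exact)
  scale <- treat_lib / control_lib
  genome_rate <- if (nrow(treat) > 0) nrow(treat) / sum(as.numeric(chrom_lengths)) else 0
  win$lambda_local <- pmax(win$control_count * scale,
                           ctrl_local * scale * width / span,
                           genome_rate * width)
  win$p_value <- ifelse(win$lambda_local > 0,
                        stats::ppois(win$treat_count - 1L, win$lambda_local,
                                     lower.tail = FALSE),
                        ifelse(win$treat_count > 0, 0, 1))
  if (nrow(treat) == 0L) win$p_value <- 1
  win$q_value <- bh_adjust(win$p_value)
  win
}

# 1 bp fragment midpoints.
read_midpoints <- function(reads) {
  mid <- (reads$start + reads$end) %/% 2L
  data.frame(chrom = reads$chrom, start = mid, end = mid + 1L,
             stringsAsFactors = FALSE)
}

# Sliding windows over every chromosome, clipped at chromosome ends.
tile_windows <- function(chrom_lengths, width, step) {
  out <- lapply(names(chrom_lengths), function(ch) {
    len <- as.integer(chrom_lengths[[ch]])
    starts <- seq.int(0L, max(0L, len - 1L), by = step)
    starts <- starts[starts < len]
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + as.integer(width), len),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Merge significant windows into peaks
#'
#' Windows with `q_value < q_threshold` are merged when overlapping or
#' book-ended; each peak carries the minimum member q-value.
#'
#' @param windows output of [window_enrichment()].
#' @param q_threshold FDR threshold (default 0.1).
#' @return data.frame of peaks: `chrom`, `start`, `end`, `q_value`, `name`.
#' @export
call_peaks <- function(windows, q_threshold = 0.1) {
  sig <- windows[windows$q_value < q_threshold, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      q_value = numeric(), name = character(),
                      stringsAsFactors = FALSE))
  }
  gr <- as_granges(sig)
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, ignore.strand = TRUE)
  qmin <- vapply(red$revmap, function(i) min(sig$q_value[i]), numeric(1))
  data.frame(chrom = as.character(GenomicRanges::seqnames(red)),
             start = GenomicRanges::start(red) - 1L,
             end = GenomicRanges::end(red),
             q_value = qmin,
             name = paste0("peak_", seq_along(red)),
             stringsAsFactors = FALSE)
}

#' Assign peaks to bound genes
#'
#' A gene is bound iff at least one peak overlaps its genic region
#' (body plus flanks) by >= 1 bp.
#'
#' @param peaks data.frame from [call_peaks()].
#' @param regions genic regions from [genic_regions()].
#' @return character vector of bound gene ids (annotation order).
#' @export
assign_bound_genes <- function(peaks, regions) {
  if (nrow(peaks) == 0L) return(character())
  hits <- GenomicRanges::findOverlaps(as_granges(regions), as_granges(peaks),
                                      minoverlap = 1L, ignore.strand = TRUE)
  regions$gene_id[sort(unique(S4Vectors::queryHits(hits)))]
}

#' Write peaks as BED (score column = -log10 q)
#' @param peaks data.frame from [call_peaks()].
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  peaks$score <- round(-log10(pmax(peaks$q_value, 1e-300)), 4)
  write_bed(peaks, path)
}
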