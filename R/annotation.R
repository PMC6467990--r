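# Gene annotation and read-interval ingestion. Internal convention: 0-based
# half-open coordinates (BED); GFF3 (1-based closed) is converted on ingest.

#' Read a gene annotation from GFF3 or BED6
#'
#' Returns one record per gene as a data.frame with columns `gene_id`,
#' `chrom`, `start`, `end`, `strand` in 0-based half-open coordinates.
#' GFF3 files are parsed with rtracklayer and filtered to `type == "gene"`;
#' 6-column BED is taken verbatim (BED is already 0-based half-open).
#'
#' @param path path to a `.gff`/`.gff3` or `.bed` file; the format is chosen
#'   by extension unless `format` is given.
#' @param format `"gff3"`, `"bed"`, or `NULL` to infer from the extension.
#' @return data.frame of gene records.
#' @export
read_annotation <- function(path, format = NULL) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path, ignore.case = TRUE)) "gff3" else "bed"
  }
  format <- match.arg(format, c("gff3", "bed"))
  if (format == "gff3") {
    gr <- rtracklayer::import(path, format = "gff3")
    gr <- gr[as.character(gr$type) == "gene"]
    if (length(gr) == 0L) stop("no records of type 'gene' in ", path)
    ids <- gr$ID
    if (is.null(ids)) ids <- gr$Name
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene records lack ID attributes: ", path)
    genes <- data.frame(
      gene_id = as.character(ids),
      chrom   = as.character(GenomicRanges::seqnames(gr)),
      start   = GenomicRanges::start(gr) - 1L,   # 1-based closed -> 0-based half-open
      end     = GenomicRanges::end(gr),
      strand  = as.character(GenomicRanges::strand(gr)),
      stringsAsFactors = FALSE
    )
  } else {
    genes <- read_bed6(path)
    names(genes)[names(genes) == "name"] <- "gene_id"
    genes <- genes[, c("gene_id", "chrom", "start", "end", "strand")]
  }
  genes$strand[!genes$strand %in% c("+", "-")] <- "+"
  validate_genes(genes)
  genes
}

# BED6 reader with line-numbered errors.
read_bed6 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(#|track|browser)", lines) & nzchar(lines)]
  if (length(lines) == 0L) stop("no records in BED file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 6L)) {
    stop("malformed BED line (need 6 columns) at line ",
         which(nf < 6L)[1L], " of ", path)
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:6))
  start <- suppressWarnings(as.integer(m[, 2L]))
  end <- suppressWarnings(as.integer(m[, 3L]))
  bad <- which(is.na(start) | is.na(end) | start < 0L | start >= end)
  if (length(bad)) {
    stop("malformed BED coordinates at line ", bad[1L], " of ", path)
  }
  data.frame(
    chrom = m[, 1L], start = start, end = end,
    name = m[, 4L], score = m[, 5L], strand = m[, 6L],
    stringsAsFactors = FALSE
  )
}

validate_genes <- function(genes) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  if (any(genes$start < 0L) || any(genes$start >= genes$end)) {
    stop("gene records must satisfy 0 <= start < end")
  }
  dup <- genes$gene_id[duplicated(genes$gene_id)]
  if (length(dup)) stop("duplicate gene_id in annotation: ", dup[1L])
  invisible(genes)
}

#' Read aligned-read intervals from BED6
#'
#' @param path BED6 file (chrom, start, end, name, score, strand), one record
#'   per uniquely mapped read.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`.
#' @export
read_reads <- function(path) {
  b <- read_bed6(path)
  b$strand[!b$strand %in% c("+", "-")] <- "+"
  b[, c("chrom", "start", "end", "strand")]
}

#' Build genic regions (gene body plus fixed flanks)
#'
#' The counting and profiling unit: the gene body extended by `flank` bp on
#' each side, clamped at 0 and (when `chrom_lengths` is given) at the
#' chromosome end.
#'
#' @param genes gene data.frame from [read_annotation()].
#' @param flank flank width in bp (default 2000).
#' @param chrom_lengths optional named integer vector of chromosome lengths.
#' @return data.frame like `genes` plus a `flank` column, coordinates widened.
#' @export
genic_regions <- function(genes, flank = 2000L, chrom_lengths = NULL) {
  validate_genes(genes)
  out <- genes
  out$start <- pmax(0L, genes$start - as.integer(flank))
  out$end <- genes$end + as.integer(flank)
  if (!is.null(chrom_lengths)) {
    lim <- chrom_lengths[out$chrom]
    if (anyNA(lim)) stop("chromosome missing from chrom_lengths: ",
                         out$chrom[which(is.na(lim))[1L]])
    out$end <- pmin(out$end, as.integer(lim))
  }
  out$flank <- as.integer(flank)
  out
}

#' Write intervals as BED6
#'
#' @param x data.frame with `chrom`, `start`, `end` and optionally `name`
#'   (or `gene_id`), `score`, `strand`.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  name <- if (!is.null(x$name)) x$name else if (!is.null(x$gene_id)) x$gene_id else "."
  score <- if (!is.null(x$score)) x$score else 0
  strand <- if (!is.null(x$strand)) x$strand else "."
  bed <- data.frame(x$chrom, x$start, x$end, name, score, strand)
  write_atomic(bed, path, col.names = FALSE)
  invisible(path)
}

# Internal: data.frame intervals -> GRanges (shift to 1-based closed).
as_granges <- function(x, seqlengths = NULL) {
  strand <- if (!is.null(x$strand)) x$strand else rep("*", nrow(x))
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end),
    strand = strand,
    seqlengths = seqlengths
  )
}

# Atomic TSV writer (temp-then-rename within the target directory).
write_atomic <- function(df, path, col.names = TRUE, sep = "\t") {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  utils::write.table(df, tmp, sep = sep, quote = FALSE,
                     row.names = FALSE, col.names = col.names)
  file.rename(tmp, path)
  invisible(path)
}
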