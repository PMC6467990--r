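# CountMatrix container: genes x samples counts with sample descriptors and
# per-gene unit lengths. A lightweight S3 list, in the spirit of a DGEList.

GENOTYPES <- c("WT", "mutant")
STAGES <- c("C0", "C14", "C14S1", "C14S7")
ASSAYS <- c("RNA", "H3", "H3K4me1", "H3K4me2", "H3K4me3", "H3K27me3",
            "TF-ChIP", "TF-control")

#' Construct a CountMatrix
#'
#' @param counts non-negative integer matrix, genes in rows (rownames =
#'   gene ids), samples in columns (colnames = sample ids).
#' @param samples data.frame with columns `sample_id`, `genotype`
#'   (WT/mutant), `stage` (C0/C14/C14S1/C14S7), `assay`, `replicate`,
#'   `library_size`; one row per column of `counts`, same order.
#' @param unit_lengths named integer vector of per-gene unit lengths in bp
#'   (genic-region length for ChIP, gene length for RNA).
#' @return object of class `count_matrix`.
#' @export
count_matrix <- function(counts, samples, unit_lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene ids as rownames and sample ids as colnames")
  }
  if (any(counts < 0)) stop("counts must be non-negative")
  storage.mode(counts) <- "integer"
  req <- c("sample_id", "genotype", "stage", "assay", "replicate", "library_size")
  if (!all(req %in% names(samples))) {
    stop("sample sheet needs columns: ", paste(req, collapse = ", "))
  }
  if (!identical(as.character(samples$sample_id), colnames(counts))) {
    stop("sample sheet order must match count matrix columns")
  }
  if (!all(samples$genotype %in% GENOTYPES)) stop("unknown genotype in sample sheet")
  if (!all(samples$stage %in% STAGES)) stop("unknown stage in sample sheet")
  if (!all(samples$assay %in% ASSAYS)) stop("unknown assay in sample sheet")
  if (any(samples$library_size <= 0)) stop("library_size must be > 0")
  key <- paste(samples$genotype, samples$stage, samples$assay, samples$replicate)
  if (anyDuplicated(key)) stop("duplicate (genotype, stage, assay, replicate)")
  unit_lengths <- unit_lengths[rownames(counts)]
  if (anyNA(unit_lengths)) stop("unit_lengths missing for some genes")
  if (any(unit_lengths <= 0)) stop("unit_lengths must be > 0")
  structure(list(counts = counts, samples = samples,
                 unit_lengths = unit_lengths),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("CountMatrix:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  cat("assays:", paste(unique(x$samples$assay), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a CountMatrix by sample descriptors
#'
#' @param cm a `count_matrix`.
#' @param genotype,stage,assay optional filters; `NULL` keeps all.
#' @return a `count_matrix` restricted to matching samples, ordered by
#'   genotype, stage, replicate.
#' @export
cm_select <- function(cm, genotype = NULL, stage = NULL, assay = NULL) {
  keep <- rep(TRUE, nrow(cm$samples))
  if (!is.null(genotype)) keep <- keep & cm$samples$genotype %in% genotype
  if (!is.null(stage)) keep <- keep & cm$samples$stage %in% stage
  if (!is.null(assay)) keep <- keep & cm$samples$assay %in% assay
  if (!any(keep)) stop("no samples match the requested descriptors")
  s <- cm$samples[keep, , drop = FALSE]
  ord <- order(match(s$genotype, GENOTYPES), match(s$stage, STAGES), s$replicate)
  s <- s[ord, , drop = FALSE]
  count_matrix(cm$counts[, s$sample_id, drop = FALSE], s, cm$unit_lengths)
}

# Replicate columns for one condition, as a genes x replicates matrix.
cm_reps <- function(cm, genotype, stage, assay) {
  sel <- cm_select(cm, genotype = genotype, stage = stage, assay = assay)
  sel$counts
}

# Library sizes for the same selection, in the same order.
cm_libsizes <- function(cm, genotype, stage, assay) {
  sel <- cm_select(cm, genotype = genotype, stage = stage, assay = assay)
  sel$samples$library_size
}

#' Write / read count matrices as TSV
#'
#' The TSV has a header of sample ids and a first column `gene_id`.
#' `read_counts_tsv()` rebuilds a `count_matrix` given the sample sheet and
#' unit lengths.
#'
#' @param cm a `count_matrix`.
#' @param path TSV path.
#' @export
write_counts_tsv <- function(cm, path) {
  df <- data.frame(gene_id = rownames(cm$counts), cm$counts,
                   check.names = FALSE)
  write_atomic(df, path)
}

#' @rdname write_counts_tsv
#' @param samples sample sheet data.frame (rows matching the TSV columns).
#' @param unit_lengths named per-gene lengths in bp.
#' @export
read_counts_tsv <- function(path, samples, unit_lengths) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene_id
  storage.mode(m) <- "integer"
  count_matrix(m, samples[match(colnames(m), samples$sample_id), , drop = FALSE],
               unit_lengths)
}

#' Write / read the sample sheet as TSV
#' @param samples sample sheet data.frame.
#' @param path TSV path.
#' @export
write_sample_sheet <- function(samples, path) write_atomic(samples, path)

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a gene set as a one-column TSV
#' @param genes character vector of gene ids.
#' @param path TSV path.
#' @export
write_gene_set <- function(genes, path) {
  write_atomic(data.frame(gene_id = genes), path)
}

#' @rdname write_gene_set
#' @export
read_gene_set <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)$gene_id
}
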