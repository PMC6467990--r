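# Programmatic fixtures: small gene models, read sets, and count matrices.

tiny_genes <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 9000L, 2000L),
    end = c(3000L, 12000L, 4000L),
    strand = c("+", "-", "+"),
    stringsAsFactors = FALSE
  )
}

random_reads <- function(n, chroms = c("chr1", "chr2"), max_pos = 20000L,
                         len_range = c(50L, 400L)) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len,
             strand = sample(c("+", "-"), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

random_units <- function(n, chroms = c("chr1", "chr2"), max_pos = 20000L) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1L
  data.frame(gene_id = sprintf("u%03d", seq_len(n)),
             chrom = sample(chroms, n, replace = TRUE),
             start = start,
             end = start + sample(100:2000, n, replace = TRUE),
             strand = "+", stringsAsFactors = FALSE)
}

# Count matrix from a named list of condition matrices (genes x replicates);
# names like "WT.C14"; all conditions share one assay.
build_cm <- function(cond_counts, libsize = 1e6, assay = "RNA",
                     unit_lengths = NULL) {
  n_genes <- nrow(cond_counts[[1]])
  gene_ids <- rownames(cond_counts[[1]])
  if (is.null(gene_ids)) gene_ids <- sprintf("g%03d", seq_len(n_genes))
  counts <- NULL
  samples <- NULL
  for (nm in names(cond_counts)) {
    gt <- strsplit(nm, ".", fixed = TRUE)[[1]][1]
    st <- strsplit(nm, ".", fixed = TRUE)[[1]][2]
    m <- cond_counts[[nm]]
    for (r in seq_len(ncol(m))) {
      sid <- paste(assay, gt, st, r, sep = "_")
      counts <- cbind(counts, m[, r])
      samples <- rbind(samples, data.frame(
        sample_id = sid, genotype = gt, stage = st, assay = assay,
        replicate = r, library_size = libsize, stringsAsFactors = FALSE))
    }
  }
  rownames(counts) <- gene_ids
  colnames(counts) <- samples$sample_id
  if (is.null(unit_lengths)) unit_lengths <- setNames(rep(1000L, n_genes),
                                                      gene_ids)
  count_matrix(counts, samples, unit_lengths)
}

# Small, fast simulation used by unit tests (not the study-scale defaults).
small_sim <- function(seed = 42, ...) {
  simulate_dataset(sim_config(n_genes = 200L, n_chroms = 2L,
                              mean_count = 40, seed = seed, ...))
}

write_gff3_fixture <- function(path) {
  writeLines(c(
    "##gff-version 3",
    "chr1\ttest\tgene\t1001\t3000\t.\t+\t.\tID=gA",
    "chr1\ttest\tmRNA\t1001\t3000\t.\t+\t.\tID=gA.1;Parent=gA",
    "chr1\ttest\tgene\t5001\t6000\t.\t-\t.\tID=gB"
  ), path)
  path
}
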