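test_that("extend_reads fixes the 5' end and yields uniform fragment length", {
  reads <- data.frame(chrom = "chr1",
                      start = c(100L, 100L, 100L),
                      end = c(175L, 175L, 350L),
                      strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
  out <- extend_reads(reads, 250L)
  expect_equal(out$start, c(100L, 0L, 100L))
  expect_equal(out$end, c(350L, 175L, 350L))
})

test_that("extend_reads is idempotent on random read sets", {
  set.seed(11)
  for (i in 1:5) {
    reads <- random_reads(200)
    once <- extend_reads(reads, 250L)
    expect_identical(extend_reads(once, 250L), once)
  }
})

test_that("count_overlaps follows the >= 1 bp multi-assignment rule", {
  units <- data.frame(gene_id = c("u1", "u2"), chrom = "chr1",
                      start = c(0L, 200L), end = c(100L, 400L),
                      strand = "+", stringsAsFactors = FALSE)
  read <- data.frame(chrom = "chr1", start = 0L, end = 250L, strand = "+",
                     stringsAsFactors = FALSE)
  expect_equal(unname(count_overlaps(read, units)), c(1L, 1L))
  expect_equal(unname(count_overlaps(read[0, ], units)), c(0L, 0L))
})

test_that("count_overlaps equals the all-pairs oracle on random fixtures", {
  set.seed(23)
  for (i in 1:10) {
    reads <- random_reads(sample(10:1000, 1))
    units <- random_units(sample(5:100, 1))
    expect_equal(unname(count_overlaps(reads, units)),
                 overlap_oracle(reads, units))
  }
})

test_that("metagene profile of exactly uniform coverage is flat", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 5000L,
                      end = 8000L, strand = "+", stringsAsFactors = FALSE)
  # back-to-back 250 bp fragments covering the whole profiled span
  starts <- seq(2000L, 11000L, by = 250L)
  reads <- data.frame(chrom = "chr1", start = starts, end = starts + 250L,
                      strand = "+", stringsAsFactors = FALSE)
  prof <- metagene_profile(reads, genes, flank = 2000L, body_bins = 100L,
                           flank_bins = 50L)
  expect_equal(length(prof$values), 200L)
  expect_true(max(abs(prof$values - mean(prof$values))) <
                0.02 * mean(prof$values))
  expect_true(all(prof$values >= 0))
})

test_that("single-read profile matches per-base brute-force rebinning", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                      end = 2000L, strand = "+", stringsAsFactors = FALSE)
  reads <- data.frame(chrom = "chr1", start = 1200L, end = 1450L,
                      strand = "+", stringsAsFactors = FALSE)
  flank <- 500L; bb <- 20L; fb <- 5L
  prof <- metagene_profile(reads, genes, flank = flank, body_bins = bb,
                           flank_bins = fb)
  # brute force: explicit per-base coverage then block means
  span <- numeric(1000L + 2L * flank)
  span[(1200 - 500 + 1):(1450 - 500)] <- 1
  block_means <- function(v, n) {
    bin <- floor((seq_along(v) - 1L) * n / length(v)) + 1L
    as.numeric(tapply(v, bin, mean))
  }
  expected <- c(block_means(span[1:500], fb),
                block_means(span[501:1500], bb),
                block_means(span[1501:2000], fb))
  expect_equal(prof$values, expected, tolerance = 1e-12)
  expect_true(all(prof$values[prof$bin_class != "body"] == 0))
})

test_that("strand-mirrored inputs give identical profiles", {
  plus_gene <- data.frame(gene_id = "gp", chrom = "chr1", start = 10000L,
                          end = 12000L, strand = "+", stringsAsFactors = FALSE)
  minus_gene <- data.frame(gene_id = "gm", chrom = "chr2", start = 10000L,
                           end = 12000L, strand = "-", stringsAsFactors = FALSE)
  set.seed(9)
  offs <- sample(0:1500, 40, replace = TRUE)
  plus_reads <- data.frame(chrom = "chr1", start = 10000L + offs,
                           end = 10000L + offs + 200L, strand = "+",
                           stringsAsFactors = FALSE)
  # mirror positions around the gene midpoint onto the minus-strand gene
  m_end <- 12000L - offs
  minus_reads <- data.frame(chrom = "chr2", start = m_end - 200L,
                            end = m_end, strand = "-",
                            stringsAsFactors = FALSE)
  p1 <- metagene_profile(plus_reads, plus_gene, flank = 1000L,
                         body_bins = 40L, flank_bins = 10L)
  p2 <- metagene_profile(minus_reads, minus_gene, flank = 1000L,
                         body_bins = 40L, flank_bins = 10L)
  expect_equal(p1$values, p2$values, tolerance = 1e-12)
})

test_that("per-base coverage conserves total signal inside the span", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 2000L,
                      end = 3000L, strand = "+", stringsAsFactors = FALSE)
  set.seed(4)
  offs <- sample(0:700, 25, replace = TRUE)
  reads <- data.frame(chrom = "chr1", start = 2100L + offs,
                      end = 2100L + offs + 150L, strand = "+",
                      stringsAsFactors = FALSE)
  # bin size 1 on body and flanks: values are the per-base coverage itself
  prof <- metagene_profile(reads, genes, flank = 500L, body_bins = 1000L,
                           flank_bins = 500L)
  expect_equal(sum(prof$values), sum(reads$end - reads$start))
})

test_that("short gene bodies are interpolated, zero genes error", {
  genes <- data.frame(gene_id = "g1", chrom = "chr1", start = 1000L,
                      end = 1010L, strand = "+", stringsAsFactors = FALSE)
  reads <- data.frame(chrom = "chr1", start = 990L, end = 1020L,
                      strand = "+", stringsAsFactors = FALSE)
  prof <- metagene_profile(reads, genes, flank = 100L, body_bins = 50L,
                           flank_bins = 10L)
  expect_length(prof$values, 70L)
  expect_true(all(prof$values[prof$bin_class == "body"] == 1))
  expect_error(metagene_profile(reads, genes[0, ], flank = 100L),
               "at least one gene")
})
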