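# Synthetic-data generator emulating a two-genotype (WT / mutant), four-stage
# (C0, C14, C14S1, C14S7) regeneration study: RNA-seq count matrices in
# biological triplicate, histone-mark ChIP read intervals in duplicate at
# C0/C14/C14S1, and a TF ChIP + control pair at C14, with an injected primed
# gene subset and full ground-truth labels.

MARK_ASSAYS <- c("H3", "H3K4me1", "H3K4me2", "H3K4me3")
CHIP_STAGES <- c("C0", "C14", "C14S1")

#' Simulation configuration
#'
#' Defaults describe the study conditions the analysis is calibrated on:
#' 2000 genes on 5 toy chromosomes, 10% primed genes (a subset of TF-bound
#' me1+me3+ genes), a 2x mutant/WT H3K4me2 elevation at C14 carried through
#' C14S1, 2x induction of primed genes at shoot induction in WT attenuated to
#' half in the mutant, 30% bound genes with 4x TF enrichment skewed 3', and
#' 70%/70% me1/me3-positive genes (~49% me1+me3+ among bound genes).
#'
#' @param n_genes number of genes.
#' @param n_chroms number of chromosomes genes are tiled on (>= 4 kb gaps so
#'   2 kb flanks never merge).
#' @param gene_length_range min/max gene body length (bp).
#' @param priming_fraction fraction of genes primed (subset of bound
#'   me1+me3+ genes).
#' @param me2_effect mutant/WT H3K4me2 multiplier on primed genes at C14,
#'   maintained at C14S1.
#' @param induction_fc WT expression fold change of primed genes at
#'   C14S1/C14S7 relative to C14.
#' @param attenuation multiplier on `induction_fc` in the mutant (1 = no
#'   priming effect on expression).
#' @param bound_fraction fraction of TF-bound genes.
#' @param binding_enrichment TF read-density fold enrichment over background
#'   on bound gene bodies.
#' @param binding_skew fraction of bound-gene TF reads placed in the 3' half
#'   of the body.
#' @param me1_fraction,me3_fraction fractions of me1+/me3+ genes.
#' @param nb_dispersion negative-binomial dispersion of RNA counts
#'   (variance = mu + dispersion * mu^2).
#' @param mean_count mean RNA baseline count per gene.
#' @param down_fraction,down_fc fraction of (non-primed) genes down-regulated
#'   upon induction in both genotypes, and their fold change.
#' @param rna_replicates,chip_replicates replicate numbers (3 and 2 in the
#'   emulated design).
#' @param assays which ChIP assays to generate (`"TF"` plus any of the mark
#'   assays); RNA is always generated.
#' @param seed integer seed; all randomness flows from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000L, n_chroms = 5L,
                       gene_length_range = c(1000L, 3000L),
                       priming_fraction = 0.1, me2_effect = 2,
                       induction_fc = 2, attenuation = 0.5,
                       bound_fraction = 0.3, binding_enrichment = 4,
                       binding_skew = 0.75,
                       me1_fraction = 0.7, me3_fraction = 0.7,
                       nb_dispersion = 0.005, mean_count = 50,
                       down_fraction = 0.1, down_fc = 0.5,
                       rna_replicates = 3L, chip_replicates = 2L,
                       assays = c(MARK_ASSAYS, "TF"), seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(n_genes >= 10L, n_chroms >= 1L,
            gene_length_range[1] > 200L,
            gene_length_range[1] <= gene_length_range[2],
            priming_fraction >= 0, priming_fraction <= 1,
            me2_effect >= 1, induction_fc > 1,
            attenuation > 0, attenuation <= 1,
            bound_fraction >= 0, bound_fraction <= 1,
            binding_enrichment > 1, binding_skew >= 0, binding_skew <= 1,
            me1_fraction >= 0, me1_fraction <= 1,
            me3_fraction >= 0, me3_fraction <= 1,
            nb_dispersion > 0, mean_count > 0,
            down_fraction >= 0, down_fraction <= 1, down_fc > 0, down_fc < 1,
            rna_replicates >= 1L, chip_replicates >= 1L)
  cfg$assays <- if (is.null(assays) || length(assays) == 0L) {
    character(0)
  } else {
    match.arg(assays, c(MARK_ASSAYS, "TF"), several.ok = TRUE)
  }
  class(cfg) <- "sim_config"
  cfg
}

# sample() without the length-1 surprise
resample <- function(x, k) x[sample.int(length(x), k)]

READ_LEN <- 175L   # emitted fragment length, pre-extension
GAP <- 5000L       # intergenic gap; > 2 * flank so genic regions never merge
DENS_HI <- 0.02    # reads/bp for a present mark
DENS_LO <- 0.001   # reads/bp for an absent mark
TF_DENS <- 0.05    # TF background reads/bp (treatment and control)

#' Simulate a complete dataset
#'
#' Generates the annotation, ground truth, RNA count matrix, per-sample ChIP
#' read intervals (fragment length 175 bp, so the 250 bp extension step is
#' exercised downstream), and the ChIP count matrix obtained by running the
#' package's own extension and overlap counting over genic regions.
#'
#' @param config a [sim_config()].
#' @return list of class `sim_dataset` with elements `genes`,
#'   `chrom_lengths`, `regions`, `rna` (count_matrix), `chip` (count_matrix
#'   or NULL), `reads` (named list of read data.frames per ChIP sample),
#'   `sample_sheet`, `truth`, `config`.
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes

  # --- gene layout -----------------------------------------------------
  lens <- sample(seq(config$gene_length_range[1], config$gene_length_range[2]),
                 n, replace = TRUE)
  chrom_of <- sort(rep_len(seq_len(config$n_chroms), n))
  start <- integer(n)
  for (ch in seq_len(config$n_chroms)) {
    idx <- which(chrom_of == ch)
    start[idx] <- GAP + c(0L, cumsum(lens[idx[-length(idx)]] + GAP))
  }
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(n)),
    chrom = paste0("chr", chrom_of),
    start = start, end = start + lens,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  chrom_lengths <- vapply(seq_len(config$n_chroms), function(ch) {
    max(genes$end[chrom_of == ch]) + GAP
  }, numeric(1))
  names(chrom_lengths) <- paste0("chr", seq_len(config$n_chroms))
  regions <- genic_regions(genes, flank = 2000L, chrom_lengths = chrom_lengths)

  # --- ground truth ----------------------------------------------------
  me1 <- me3 <- bound <- primed <- down <- logical(n)
  me1[resample(seq_len(n), round(config$me1_fraction * n))] <- TRUE
  me3[resample(seq_len(n), round(config$me3_fraction * n))] <- TRUE
  bound[resample(seq_len(n), round(config$bound_fraction * n))] <- TRUE
  n_primed <- round(config$priming_fraction * n)
  eligible <- which(bound & me1 & me3)
  if (length(eligible) < n_primed) {
    stop("infeasible config: only ", length(eligible),
         " bound me1+me3+ genes available for ", n_primed, " primed genes")
  }
  if (n_primed > 0L) primed[resample(eligible, n_primed)] <- TRUE
  down_pool <- which(!primed)
  n_down <- min(round(config$down_fraction * n), length(down_pool))
  if (n_down > 0L) down[resample(down_pool, n_down)] <- TRUE

  # per-gene intrinsic factors (shared across genotypes and replicates)
  expr_factor <- stats::rlnorm(n, meanlog = -0.125, sdlog = 0.5)
  mark_factor <- lapply(setNames(MARK_ASSAYS, MARK_ASSAYS), function(a) {
    stats::rlnorm(n, meanlog = -0.125, sdlog = 0.5)
  })
  # gene-specific H3K4me2 level at C0 relative to C14 (callus-formation gain)
  me2_c0 <- stats::rlnorm(n, meanlog = log(0.7), sdlog = 0.6)

  base_mu <- config$mean_count * ifelse(me3, 1.176, 0.588) * expr_factor

  # --- RNA counts ------------------------------------------------------
  expr_mult <- function(genotype, stage) {
    m <- rep(1, n)
    if (stage %in% c("C14S1", "C14S7")) {
      fc <- config$induction_fc *
        if (genotype == "mutant") config$attenuation else 1
      m[primed] <- fc
      m[down] <- config$down_fc
    }
    m
  }
  # RNA library size is the mapped-library depth (of which annotated-gene
  # counts are roughly half), not the column sum: per-million normalization
  # against mapped depth does not inherit the compositional shift that
  # induced genes cause in the counted total.
  rna_counts <- NULL
  rna_samples <- NULL
  for (g in GENOTYPES) for (s in STAGES) for (r in seq_len(config$rna_replicates)) {
    jit <- stats::rlnorm(1, -0.00125, 0.05)   # per-sample depth variation
    mu <- base_mu * expr_mult(g, s) * jit
    cnt <- stats::rnbinom(n, mu = mu, size = 1 / config$nb_dispersion)
    rna_counts <- cbind(rna_counts, cnt)
    rna_samples <- rbind(rna_samples, data.frame(
      sample_id = paste("RNA", g, s, paste0("r", r), sep = "_"),
      genotype = g, stage = s, assay = "RNA", replicate = r,
      library_size = round(2 * n * config$mean_count * jit),
      stringsAsFactors = FALSE))
  }
  rownames(rna_counts) <- genes$gene_id
  colnames(rna_counts) <- rna_samples$sample_id
  rna <- count_matrix(rna_counts, rna_samples,
                      setNames(lens, genes$gene_id))

  # --- ChIP reads ------------------------------------------------------
  region_len <- regions$end - regions$start
  reads <- list()
  chip_samples <- NULL
  mark_assays <- intersect(MARK_ASSAYS, config$assays)
  for (a in mark_assays) {
    dens <- switch(a,
      "H3" = rep(DENS_HI, n),
      "H3K4me1" = ifelse(me1, DENS_HI, DENS_LO),
      "H3K4me3" = ifelse(me3, DENS_HI, DENS_LO),
      "H3K4me2" = rep(DENS_HI, n))
    for (g in GENOTYPES) for (s in CHIP_STAGES) {
      mult <- rep(1, n)
      if (a == "H3K4me2") {
        if (s == "C0") mult <- me2_c0
        if (g == "mutant" && s %in% c("C14", "C14S1")) {
          mult[primed] <- mult[primed] * config$me2_effect
        }
      }
      intensity <- dens * region_len * mark_factor[[a]] * mult
      for (r in seq_len(config$chip_replicates)) {
        sid <- paste(a, g, s, paste0("r", r), sep = "_")
        reads[[sid]] <- place_gene_reads(genes, stats::rpois(n, intensity))
        chip_samples <- rbind(chip_samples, data.frame(
          sample_id = sid, genotype = g, stage = s, assay = a, replicate = r,
          library_size = nrow(reads[[sid]]), stringsAsFactors = FALSE))
      }
    }
  }
  if ("TF" %in% config$assays) {
    extra <- ifelse(bound, (config$binding_enrichment - 1) * TF_DENS * lens, 0)
    treat <- rbind(place_background_reads(chrom_lengths, TF_DENS),
                   place_skewed_reads(genes, stats::rpois(n, extra),
                                      config$binding_skew))
    ctrl <- place_background_reads(chrom_lengths, TF_DENS)
    reads[["TF-ChIP_mutant_C14_r1"]] <- treat
    reads[["TF-control_WT_C14_r1"]] <- ctrl
    chip_samples <- rbind(chip_samples, data.frame(
      sample_id = c("TF-ChIP_mutant_C14_r1", "TF-control_WT_C14_r1"),
      genotype = c("mutant", "WT"), stage = "C14",
      assay = c("TF-ChIP", "TF-control"), replicate = 1L,
      library_size = c(nrow(treat), nrow(ctrl)), stringsAsFactors = FALSE))
  }

  # ChIP count matrix over genic regions, via the package's own pipeline
  chip <- NULL
  if (length(mark_assays) > 0L) {
    ids <- chip_samples$sample_id[chip_samples$assay %in% mark_assays]
    cols <- vapply(ids, function(sid) {
      count_overlaps(extend_reads(reads[[sid]], 250L, chrom_lengths), regions)
    }, integer(n))
    chip <- count_matrix(cols,
                         chip_samples[match(ids, chip_samples$sample_id), ],
                         setNames(region_len, genes$gene_id))
  }

  truth <- list(
    genes = data.frame(
      gene_id = genes$gene_id, length = lens,
      primed = primed, bound = bound, me1 = me1, me3 = me3,
      me_class = paste0("me1", ifelse(me1, "+", "-"),
                        "me3", ifelse(me3, "+", "-")),
      induced_s1 = primed, down_s1 = down,
      baseline_mean = base_mu,
      me2_multiplier = ifelse(primed, config$me2_effect, 1),
      stringsAsFactors = FALSE),
    seed = config$seed,
    config = unclass(config)
  )

  structure(list(genes = genes, chrom_lengths = chrom_lengths,
                 regions = regions, rna = rna, chip = chip, reads = reads,
                 sample_sheet = rbind(rna_samples, chip_samples),
                 truth = truth, config = config),
            class = "sim_dataset")
}

# Uniform read placement inside gene bodies: counts[i] reads in gene i.
place_gene_reads <- function(genes, counts) {
  idx <- rep.int(seq_len(nrow(genes)), counts)
  total <- length(idx)
  width <- genes$end[idx] - genes$start[idx] - READ_LEN
  start <- genes$start[idx] + floor(stats::runif(total) * pmax(width, 1L))
  data.frame(chrom = genes$chrom[idx], start = as.integer(start),
             end = as.integer(start + READ_LEN),
             strand = sample(c("+", "-"), total, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Bound-gene TF reads with a fraction `skew` placed in the 3' half of the body.
place_skewed_reads <- function(genes, counts, skew) {
  idx <- rep.int(seq_len(nrow(genes)), counts)
  total <- length(idx)
  if (total == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  half <- (genes$end[idx] - genes$start[idx]) %/% 2L
  in3 <- stats::runif(total) < skew
  plus <- genes$strand[idx] == "+"
  # 3' half is the right half for + genes, the left half for - genes
  right <- (in3 & plus) | (!in3 & !plus)
  lo <- ifelse(right, genes$start[idx] + half, genes$start[idx])
  start <- lo + floor(stats::runif(total) * pmax(half - READ_LEN, 1L))
  data.frame(chrom = genes$chrom[idx], start = as.integer(start),
             end = as.integer(start + READ_LEN),
             strand = sample(c("+", "-"), total, replace = TRUE),
             stringsAsFactors = FALSE)
}

# Uniform genome-wide background at `dens` reads per bp.
place_background_reads <- function(chrom_lengths, dens) {
  per_chrom <- stats::rpois(length(chrom_lengths), dens * chrom_lengths)
  chrom <- rep.int(names(chrom_lengths), per_chrom)
  total <- sum(per_chrom)
  start <- floor(stats::runif(total) *
                   (rep.int(chrom_lengths, per_chrom) - READ_LEN))
  data.frame(chrom = chrom, start = as.integer(start),
             end = as.integer(start + READ_LEN),
             strand = sample(c("+", "-"), total, replace = TRUE),
             stringsAsFactors = FALSE)
}

#' Null dataset (no priming, genotypes exchangeable)
#'
#' Same generator with `priming_fraction = 0`, `me2_effect = 1` and
#' `attenuation = 1`: the two genotypes are statistically exchangeable, used
#' for calibration suites. TF binding (a within-genotype contrast) is kept.
#'
#' @param config a [sim_config()]; the three null overrides are applied on
#'   top of it.
#' @return a `sim_dataset`.
#' @export
null_dataset <- function(config = sim_config()) {
  cfg <- unclass(config)
  cfg$priming_fraction <- 0
  cfg$me2_effect <- 1
  cfg$attenuation <- 1
  simulate_dataset(do.call(sim_config, cfg))
}

#' Write a simulated dataset to disk
#'
#' Emits `annotation.bed`, `reads/<sample>.bed` per ChIP sample,
#' `rna_counts.tsv`, `chip_counts.tsv`, `sample_sheet.tsv`, and `truth.json`
#' (ground truth plus config echo).
#'
#' @param ds a `sim_dataset`.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of written paths.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "reads"), showWarnings = FALSE)
  paths <- c(file.path(dir, "annotation.bed"),
             file.path(dir, "sample_sheet.tsv"),
             file.path(dir, "rna_counts.tsv"),
             file.path(dir, "truth.json"))
  write_bed(ds$genes, paths[1])
  write_sample_sheet(ds$sample_sheet, paths[2])
  write_counts_tsv(ds$rna, paths[3])
  jsonlite::write_json(ds$truth, paths[4], auto_unbox = TRUE, digits = NA)
  if (!is.null(ds$chip)) {
    p <- file.path(dir, "chip_counts.tsv")
    write_counts_tsv(ds$chip, p)
    paths <- c(paths, p)
  }
  for (sid in names(ds$reads)) {
    p <- file.path(dir, "reads", paste0(sid, ".bed"))
    write_bed(ds$reads[[sid]], p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
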