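# Orchestration: re-entrant subcommands over an output directory, a JSON run
# manifest (config + input checksums + package version, no wall clock so
# identical runs are byte-identical), and stderr logging with timestamps.

#' Per-gene log2(mutant/WT) ratio of replicate-averaged normalized values
#'
#' Normalizes all samples of one assay together (RPKM by default), applies
#' the half-minimum pseudocount over that whole matrix, averages replicates
#' per condition, and returns the per-gene log2 ratio mutant/WT at `stage`.
#'
#' @param cm a `count_matrix`.
#' @param assay assay name.
#' @param stage stage label.
#' @param scale `"RPKM"` or `"RPM"`.
#' @return named numeric vector of log2 ratios.
#' @export
genotype_log2_ratio <- function(cm, assay, stage, scale = c("RPKM", "RPM")) {
  scale <- match.arg(scale)
  sel <- cm_select(cm, assay = assay)
  m <- if (scale == "RPKM") {
    rpkm(sel$counts, sel$unit_lengths, sel$samples$library_size)
  } else {
    rpm(sel$counts, sel$samples$library_size)
  }
  m <- add_half_min_pseudocount(m)
  num <- sel$samples$genotype == "mutant" & sel$samples$stage == stage
  den <- sel$samples$genotype == "WT" & sel$samples$stage == stage
  if (!any(num) || !any(den)) stop("missing genotype samples at stage ", stage)
  log2_ratio(m[, num, drop = FALSE], m[, den, drop = FALSE])
}

pc_log <- function(level, ..., min_level = "info") {
  levels <- c(debug = 1L, info = 2L, warn = 3L)
  if (levels[[level]] >= levels[[min_level]]) {
    message(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), " [", level, "] ", ...)
  }
}

#' Run the analysis pipeline
#'
#' Subcommands (each re-entrant, reading only its declared inputs from
#' `config$outdir`):
#' \describe{
#'   \item{simulate}{generate a synthetic dataset under `outdir/data/`.}
#'   \item{count}{recount ChIP reads over genic regions from the BED files.}
#'   \item{normalize}{write RPM and RPKM tables.}
#'   \item{bind}{call TF peaks and the bound gene set.}
#'   \item{respond}{stage-response (UGs/DGs) sets.}
#'   \item{hyper}{hyper-H3K4me2 gene set.}
#'   \item{prime}{mark-change groups, lag tests, stratified analysis.}
#'   \item{targets}{down-in-mutant set, four-set intersection, Venn table.}
#'   \item{report}{assemble the JSON priming report (errors if an upstream
#'     artifact is missing).}
#'   \item{all}{chain everything above, then write the manifest.}
#' }
#'
#' @param config a list (or path to a YAML file) with `outdir`, optional
#'   `seed`, and optional override blocks `sim` (see [sim_config()]),
#'   `thresholds` (see [analysis_thresholds()]), `caller` (`width`, `step`)
#'   and `log_level` (`"debug"`, `"info"`, `"warn"`).
#' @param subcommand one of the subcommands above.
#' @return invisibly, the path of the manifest (or of the subcommand's main
#'   artifact).
#' @export
run_pipeline <- function(config, subcommand = "all") {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$outdir)) stop("config$outdir is required")
  subcommand <- match.arg(subcommand,
                          c("simulate", "count", "normalize", "bind",
                            "respond", "hyper", "prime", "targets",
                            "report", "all"))
  th <- do.call(analysis_thresholds, config$thresholds %||% list())
  lvl <- config$log_level %||% "info"
  outdir <- config$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  steps <- if (subcommand == "all") {
    c("simulate", "count", "normalize", "bind", "respond", "hyper",
      "prime", "targets", "report")
  } else subcommand
  for (s in steps) {
    pc_log("info", "step: ", s, min_level = lvl)
    switch(s,
      simulate = step_simulate(config, outdir),
      count = step_count(outdir, th),
      normalize = step_normalize(outdir, th),
      bind = step_bind(config, outdir, th),
      respond = step_respond(outdir, th),
      hyper = step_hyper(outdir, th),
      prime = step_prime(outdir, th),
      targets = step_targets(outdir, th),
      report = step_report(outdir, th))
  }
  manifest <- write_manifest(config, outdir, steps)
  pc_log("info", "done; manifest at ", manifest, min_level = lvl)
  invisible(manifest)
}

need_file <- function(path, producer) {
  if (!file.exists(path)) {
    stop("missing artifact '", path, "'; run the '", producer,
         "' step first", call. = FALSE)
  }
  path
}

load_dataset <- function(outdir, th) {
  data_dir <- file.path(outdir, "data")
  genes <- read_annotation(need_file(file.path(data_dir, "annotation.bed"),
                                     "simulate"))
  sheet <- read_sample_sheet(need_file(file.path(data_dir, "sample_sheet.tsv"),
                                       "simulate"))
  chrom_lengths <- tapply(genes$end + 5000L, genes$chrom, max)
  regions <- genic_regions(genes, flank = th$flank,
                           chrom_lengths = chrom_lengths)
  rna <- read_counts_tsv(need_file(file.path(data_dir, "rna_counts.tsv"),
                                   "simulate"),
                         sheet, setNames(genes$end - genes$start, genes$gene_id))
  list(genes = genes, sheet = sheet, chrom_lengths = chrom_lengths,
       regions = regions, rna = rna, data_dir = data_dir)
}

load_chip <- function(outdir, th) {
  d <- load_dataset(outdir, th)
  path <- need_file(file.path(outdir, "counts", "chip_counts.tsv"), "count")
  region_len <- setNames(d$regions$end - d$regions$start, d$regions$gene_id)
  d$chip <- read_counts_tsv(path, d$sheet, region_len)
  d
}

step_simulate <- function(config, outdir) {
  sim_args <- config$sim %||% list()
  if (!is.null(config$seed)) sim_args$seed <- config$seed
  ds <- simulate_dataset(do.call(sim_config, sim_args))
  write_dataset(ds, file.path(outdir, "data"))
}

step_count <- function(outdir, th) {
  d <- load_dataset(outdir, th)
  reads_dir <- file.path(d$data_dir, "reads")
  beds <- list.files(reads_dir, pattern = "\\.bed$", full.names = TRUE)
  mark <- beds[!grepl("^TF", basename(beds))]
  if (length(mark) == 0L) stop("no mark ChIP BED files under ", reads_dir)
  sids <- sub("\\.bed$", "", basename(mark))
  ord <- order(match(sids, d$sheet$sample_id))
  mark <- mark[ord]; sids <- sids[ord]
  cols <- vapply(mark, function(p) {
    count_overlaps(extend_reads(read_reads(p), th$fragment_length,
                                d$chrom_lengths), d$regions)
  }, integer(nrow(d$regions)))
  colnames(cols) <- sids
  cm <- count_matrix(cols, d$sheet[match(sids, d$sheet$sample_id), ,
                                   drop = FALSE],
                     setNames(d$regions$end - d$regions$start,
                              d$regions$gene_id))
  dir.create(file.path(outdir, "counts"), showWarnings = FALSE)
  write_counts_tsv(cm, file.path(outdir, "counts", "chip_counts.tsv"))
}

step_normalize <- function(outdir, th) {
  d <- load_chip(outdir, th)
  dir.create(file.path(outdir, "normalized"), showWarnings = FALSE)
  for (nm in c("rna", "chip")) {
    cm <- d[[nm]]
    m_rpm <- rpm(cm$counts, cm$samples$library_size)
    m_rpkm <- rpkm(cm$counts, cm$unit_lengths, cm$samples$library_size)
    write_atomic(data.frame(gene_id = rownames(cm$counts), m_rpm,
                            check.names = FALSE),
                 file.path(outdir, "normalized", paste0(nm, "_rpm.tsv")))
    write_atomic(data.frame(gene_id = rownames(cm$counts), m_rpkm,
                            check.names = FALSE),
                 file.path(outdir, "normalized", paste0(nm, "_rpkm.tsv")))
  }
}

step_bind <- function(config, outdir, th) {
  d <- load_dataset(outdir, th)
  reads_dir <- file.path(d$data_dir, "reads")
  treat_p <- list.files(reads_dir, pattern = "^TF-ChIP.*\\.bed$",
                        full.names = TRUE)
  ctrl_p <- list.files(reads_dir, pattern = "^TF-control.*\\.bed$",
                       full.names = TRUE)
  if (length(treat_p) == 0L || length(ctrl_p) == 0L) {
    stop("TF ChIP/control BED files not found under ", reads_dir)
  }
  caller <- config$caller %||% list()
  treat <- extend_reads(read_reads(treat_p[1]), th$fragment_length,
                        d$chrom_lengths)
  ctrl <- extend_reads(read_reads(ctrl_p[1]), th$fragment_length,
                       d$chrom_lengths)
  win <- window_enrichment(treat, ctrl, d$chrom_lengths,
                           width = caller$width %||% 500L,
                           step = caller$step %||% 250L)
  peaks <- call_peaks(win, th$binding_q)
  bound <- assign_bound_genes(peaks, d$regions)
  dir.create(file.path(outdir, "binding"), showWarnings = FALSE)
  write_peaks(peaks, file.path(outdir, "binding", "peaks.bed"))
  write_gene_set(bound, file.path(outdir, "binding", "bound_genes.tsv"))
}

step_respond <- function(outdir, th) {
  d <- load_dataset(outdir, th)
  sets <- stage_response_sets(d$rna, th)
  dir.create(file.path(outdir, "sets"), showWarnings = FALSE)
  for (nm in c("UGs_S1", "DGs_S1", "UGs_S7", "DGs_S7")) {
    write_gene_set(sets[[nm]], file.path(outdir, "sets", paste0(nm, ".tsv")))
  }
}

step_hyper <- function(outdir, th) {
  d <- load_chip(outdir, th)
  hy <- hyper_mark_genes(d$chip, "H3K4me2", "C14", th)
  dir.create(file.path(outdir, "sets"), showWarnings = FALSE)
  write_gene_set(hy$genes, file.path(outdir, "sets", "hyper_me2_C14.tsv"))
  write_atomic(hy$table, file.path(outdir, "sets", "hyper_me2_C14_table.tsv"))
}

step_prime <- function(outdir, th) {
  d <- load_chip(outdir, th)
  bound <- read_gene_set(need_file(file.path(outdir, "binding",
                                             "bound_genes.tsv"), "bind"))
  delta_me2 <- genotype_log2_ratio(d$chip, "H3K4me2", "C14")
  expr_c14 <- genotype_log2_ratio(d$rna, "RNA", "C14")
  expr_s1 <- genotype_log2_ratio(d$rna, "RNA", "C14S1")
  groups <- mark_change_groups(delta_me2, th$group_bounds)
  lag <- lag_association_test(groups, expr_c14, expr_s1)
  me1 <- cm_mean_norm(d$chip, "WT", "C14", "H3K4me1", "RPKM")
  me3 <- cm_mean_norm(d$chip, "WT", "C14", "H3K4me3", "RPKM")
  states <- me_state_classify(me1, me3, th$me_state_rpkm)
  strat <- stratified_lag_analysis(bound, states, delta_me2, expr_c14,
                                   expr_s1, th$group_bounds)
  dir.create(file.path(outdir, "priming"), showWarnings = FALSE)
  write_atomic(data.frame(gene_id = names(groups), group = groups,
                          delta_me2 = delta_me2,
                          expr_ratio_C14 = expr_c14[names(groups)],
                          expr_ratio_C14S1 = expr_s1[names(groups)]),
               file.path(outdir, "priming", "groups.tsv"))
  write_atomic(lag, file.path(outdir, "priming", "lag_tests.tsv"))
  write_atomic(strat$summary,
               file.path(outdir, "priming", "stratified_summary.tsv"))
  cors <- data.frame(stage = c("C14", "C14S1"),
                     r = c(safe_cor(delta_me2, expr_c14[names(delta_me2)]),
                           safe_cor(delta_me2, expr_s1[names(delta_me2)])))
  write_atomic(cors, file.path(outdir, "priming", "scatter_correlations.tsv"))
}

step_targets <- function(outdir, th) {
  d <- load_dataset(outdir, th)
  hyper <- read_gene_set(need_file(file.path(outdir, "sets",
                                             "hyper_me2_C14.tsv"), "hyper"))
  ugs <- read_gene_set(need_file(file.path(outdir, "sets", "UGs_S1.tsv"),
                                 "respond"))
  bound <- read_gene_set(need_file(file.path(outdir, "binding",
                                             "bound_genes.tsv"), "bind"))
  down <- down_in_mutant_set(d$rna, "C14S1", th)
  dir.create(file.path(outdir, "sets"), showWarnings = FALSE)
  write_gene_set(down$genes, file.path(outdir, "sets",
                                       "down_in_mutant_S1.tsv"))
  sel <- select_primed_targets(hyper, ugs, down$genes, bound)
  write_gene_set(sel$targets, file.path(outdir, "sets",
                                        "selected_targets.tsv"))
  write_atomic(sel$venn, file.path(outdir, "sets", "venn.tsv"))
  write_atomic(sel$membership, file.path(outdir, "sets", "membership.tsv"))
}

step_report <- function(outdir, th) {
  d <- load_dataset(outdir, th)
  paths <- list(
    lag = file.path(outdir, "priming", "lag_tests.tsv"),
    strat = file.path(outdir, "priming", "stratified_summary.tsv"),
    cors = file.path(outdir, "priming", "scatter_correlations.tsv"),
    targets = file.path(outdir, "sets", "selected_targets.tsv"),
    venn = file.path(outdir, "sets", "venn.tsv"),
    bound = file.path(outdir, "binding", "bound_genes.tsv"),
    hyper = file.path(outdir, "sets", "hyper_me2_C14.tsv"),
    ugs_s1 = file.path(outdir, "sets", "UGs_S1.tsv")
  )
  for (nm in names(paths)) {
    need_file(paths[[nm]], switch(nm, lag = , strat = , cors = "prime",
                                  targets = , venn = "targets",
                                  bound = "bind", hyper = "hyper",
                                  ugs_s1 = "respond"))
  }
  read_tsv <- function(p) utils::read.table(p, header = TRUE, sep = "\t",
                                            stringsAsFactors = FALSE)
  targets <- read_gene_set(paths$targets)
  report <- list(
    n_genes = nrow(d$genes),
    sets = list(hyper_me2_C14 = length(read_gene_set(paths$hyper)),
                UGs_S1 = length(read_gene_set(paths$ugs_s1)),
                bound = length(read_gene_set(paths$bound)),
                selected_targets = length(targets)),
    lag_tests = read_tsv(paths$lag),
    stratified = read_tsv(paths$strat),
    scatter_correlations = read_tsv(paths$cors),
    venn = read_tsv(paths$venn),
    selected_targets = targets
  )
  if (length(targets) > 0L) {
    rel <- relative_expression_table(d$rna, targets)
    write_atomic(data.frame(gene_id = rownames(rel$zscores), rel$zscores,
                            check.names = FALSE),
                 file.path(outdir, "target_expression_zscores.tsv"))
    report$target_expression <- as.data.frame(rel$relative)
  }
  tmp <- tempfile(tmpdir = outdir, fileext = ".json.tmp")
  jsonlite::write_json(report, tmp, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  file.rename(tmp, file.path(outdir, "priming_report.json"))
}

write_manifest <- function(config, outdir, steps) {
  data_files <- sort(list.files(file.path(outdir, "data"), recursive = TRUE,
                                full.names = TRUE))
  sums <- if (length(data_files)) {
    s <- tools::md5sum(data_files)
    names(s) <- sub("^.*/(data/)", "\\1", names(s))
    as.list(s)
  } else list()
  manifest <- list(
    package_version = as.character(utils::packageVersion("primedchip")),
    config = config[setdiff(names(config), "outdir")],
    steps = steps,
    input_checksums = sums
  )
  path <- file.path(outdir, "manifest.json")
  tmp <- tempfile(tmpdir = outdir, fileext = ".json.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, path)
  path
}
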