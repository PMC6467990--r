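# The integrative priming analysis: stage-response gene sets, hyper-mark
# detection, mark-change grouping with stage-lagged Wilcoxon tests, me-state
# stratification, and primed-target selection.

#' Analysis thresholds
#'
#' Bundles the cutoffs of the workflow: differential expression is called at
#' BH q < `deg_p` with fold change > `deg_fc_up` (up) or < `deg_fc_down`
#' (down); hyper-mark genes at raw p < `hyper_p` with mutant/WT ratio >
#' `hyper_ratio`; TF binding at BH q < `binding_q`; an H3K4me1/me3 mark is
#' "present" above `me_state_rpkm` RPKM; genic regions use `flank` bp and
#' reads are extended to `fragment_length` bp; `group_bounds` are the log2
#' mark-change cut points separating groups i / ii / iii.
#'
#' @param deg_fc_up,deg_fc_down,deg_p DEG thresholds.
#' @param hyper_ratio,hyper_p hyper-mark thresholds.
#' @param binding_q binding-call FDR.
#' @param me_state_rpkm me-state presence threshold (RPKM, strict >).
#' @param flank genic-region flank (bp).
#' @param fragment_length ChIP read extension target (bp).
#' @param group_bounds numeric length-2, log2-scale group cut points.
#' @return list of class `analysis_thresholds`.
#' @export
analysis_thresholds <- function(deg_fc_up = 1.25, deg_fc_down = 0.8,
                                deg_p = 0.01, hyper_ratio = 1.5,
                                hyper_p = 0.01, binding_q = 0.1,
                                me_state_rpkm = 20, flank = 2000L,
                                fragment_length = 250L,
                                group_bounds = c(0, 1)) {
  th <- list(deg_fc_up = deg_fc_up, deg_fc_down = deg_fc_down, deg_p = deg_p,
             hyper_ratio = hyper_ratio, hyper_p = hyper_p,
             binding_q = binding_q, me_state_rpkm = me_state_rpkm,
             flank = as.integer(flank),
             fragment_length = as.integer(fragment_length),
             group_bounds = group_bounds)
  stopifnot(all(unlist(th[c("deg_fc_up", "deg_p", "hyper_ratio", "hyper_p",
                            "binding_q", "me_state_rpkm", "flank",
                            "fragment_length")]) > 0),
            th$deg_fc_down > 0, th$deg_fc_down < 1, th$deg_fc_up > 1,
            length(group_bounds) == 2L, group_bounds[1] < group_bounds[2])
  class(th) <- "analysis_thresholds"
  th
}

# Paired test of condition a over condition b for one assay, BH-adjusted.
condition_test <- function(cm, assay, a_genotype, a_stage, b_genotype, b_stage) {
  a <- cm_reps(cm, a_genotype, a_stage, assay)
  b <- cm_reps(cm, b_genotype, b_stage, assay)
  if (ncol(a) != ncol(b)) stop("unequal replicate numbers for paired test")
  res <- paired_count_test_all(a, b,
                               cm_libsizes(cm, a_genotype, a_stage, assay),
                               cm_libsizes(cm, b_genotype, b_stage, assay))
  res$q_value <- bh_adjust(res$p_value)
  res
}

#' Stage-response gene sets (UGs / DGs)
#'
#' Compares wild-type expression before and after shoot induction (C14 vs
#' C14S1 and C14 vs C14S7) gene by gene with the paired count test, adjusts
#' with BH, and calls up-regulated (q < deg_p, FC > deg_fc_up) and
#' down-regulated (q < deg_p, FC < deg_fc_down) sets.
#'
#' @param rna a `count_matrix` containing WT RNA samples at C14, C14S1, C14S7.
#' @param thresholds an [analysis_thresholds()] object.
#' @return list with gene-id vectors `UGs_S1`, `DGs_S1`, `UGs_S7`, `DGs_S7`
#'   and the per-gene test `tables` for each comparison.
#' @export
stage_response_sets <- function(rna, thresholds = analysis_thresholds()) {
  tables <- list()
  sets <- list()
  for (stage in c("C14S1", "C14S7")) {
    res <- condition_test(rna, "RNA", "WT", stage, "WT", "C14")
    tag <- if (stage == "C14S1") "S1" else "S7"
    tables[[tag]] <- res
    sig <- res$q_value < thresholds$deg_p
    sets[[paste0("UGs_", tag)]] <-
      res$gene_id[sig & res$effect > thresholds$deg_fc_up]
    sets[[paste0("DGs_", tag)]] <-
      res$gene_id[sig & res$effect < thresholds$deg_fc_down]
  }
  c(sets, list(tables = tables))
}

#' Hyper-mark genes (mutant over wild type for one histone mark)
#'
#' Runs the paired count test mutant vs WT on genic-region counts of the
#' given assay at one stage; the hyper set is genes with raw p < `hyper_p`
#' and pseudocounted RPM ratio mutant/WT > `hyper_ratio`. Generic over assay,
#' so the same operation serves H3K4me2 and H3K27me3.
#'
#' @param cm a `count_matrix` with ChIP duplicates for both genotypes.
#' @param assay assay name (e.g. `"H3K4me2"`).
#' @param stage stage to compare at (default `"C14"`).
#' @param thresholds an [analysis_thresholds()] object.
#' @return list with `genes` (hyper set) and the per-gene `table`.
#' @export
hyper_mark_genes <- function(cm, assay = "H3K4me2", stage = "C14",
                             thresholds = analysis_thresholds()) {
  res <- condition_test(cm, assay, "mutant", stage, "WT", stage)
  hyper <- res$gene_id[res$p_value < thresholds$hyper_p &
                         res$effect > thresholds$hyper_ratio]
  list(genes = hyper, table = res)
}

#' Group genes by their log2 mark change
#'
#' Groups on the log2(mutant/WT) mark change: i below the lower bound, ii on
#' the closed middle interval, iii above the upper bound (default bounds 0
#' and 1; boundary values fall in ii so the groups partition the universe).
#'
#' @param delta_me2 named numeric vector of log2 ratios.
#' @param bounds numeric length-2 cut points.
#' @return named character vector with values `"i"`, `"ii"`, `"iii"`.
#' @export
mark_change_groups <- function(delta_me2, bounds = c(0, 1)) {
  g <- ifelse(delta_me2 < bounds[1], "i",
              ifelse(delta_me2 <= bounds[2], "ii", "iii"))
  setNames(g, names(delta_me2))
}

#' Stage-lagged association test per mark-change group
#'
#' For each group, a paired Wilcoxon signed-rank test across genes of the
#' expression log2 ratios (mutant/WT) at C14 versus C14S1 — a small p means
#' the expression defect differs between the stages, the lag signature —
#' plus one-sample tests of each stage's ratios against zero. Groups with
#' fewer than 2 genes are reported as NA rows.
#'
#' @param groups output of [mark_change_groups()].
#' @param expr_ratio_C14,expr_ratio_C14S1 named numeric vectors of per-gene
#'   expression log2 ratios.
#' @return data.frame with one row per group: `group`, `n`, `W`, `p_value`,
#'   `minus_log10_p`, `p_C14_vs0`, `p_C14S1_vs0`.
#' @export
lag_association_test <- function(groups, expr_ratio_C14, expr_ratio_C14S1) {
  rows <- lapply(c("i", "ii", "iii"), function(g) {
    ids <- names(groups)[groups == g]
    if (length(ids) < 2L) {
      return(data.frame(group = g, n = length(ids), W = NA_real_,
                        p_value = NA_real_, minus_log10_p = NA_real_,
                        p_C14_vs0 = NA_real_, p_C14S1_vs0 = NA_real_))
    }
    w <- wilcoxon_signed_rank(expr_ratio_C14[ids], expr_ratio_C14S1[ids])
    data.frame(group = g, n = length(ids), W = w$statistic,
               p_value = w$p_value,
               minus_log10_p = -log10(max(w$p_value, 1e-300)),
               p_C14_vs0 = wilcoxon_signed_rank(expr_ratio_C14[ids])$p_value,
               p_C14S1_vs0 = wilcoxon_signed_rank(expr_ratio_C14S1[ids])$p_value)
  })
  do.call(rbind, rows)
}

#' Classify genes by H3K4me1/H3K4me3 presence
#'
#' A mark is present when its RPKM strictly exceeds `threshold`; the four
#' combinations partition the gene universe.
#'
#' @param me1_rpkm,me3_rpkm named per-gene RPKM vectors (same genes).
#' @param threshold presence threshold (default 20 RPKM).
#' @return named character vector with values `"me1-me3-"`, `"me1+me3-"`,
#'   `"me1-me3+"`, `"me1+me3+"`.
#' @export
me_state_classify <- function(me1_rpkm, me3_rpkm, threshold = 20) {
  stopifnot(length(me1_rpkm) == length(me3_rpkm))
  lab <- paste0("me1", ifelse(me1_rpkm > threshold, "+", "-"),
                "me3", ifelse(me3_rpkm > threshold, "+", "-"))
  setNames(lab, names(me1_rpkm))
}

# Generic presence classification over any set of marks (me1/me2/me3 ...):
# returns the 2^k combination label per gene.
mark_presence_classes <- function(rpkm_list, threshold = 20) {
  stopifnot(length(rpkm_list) >= 1L)
  labs <- mapply(function(nm, v) paste0(nm, ifelse(v > threshold, "+", "-")),
                 names(rpkm_list), rpkm_list, SIMPLIFY = FALSE)
  setNames(do.call(paste0, labs), names(rpkm_list[[1L]]))
}

#' Stratified lag analysis over me-state classes of bound genes
#'
#' Restricts to TF-bound genes and, within each me-state class, applies
#' [mark_change_groups()] and [lag_association_test()], and reports the
#' Pearson correlation between the mark change and the expression change at
#' each stage. The priming signature — negative correlation appearing only
#' at the post-induction stage — is expected to concentrate in the class
#' where the mark change was injected or observed.
#'
#' @param bound character vector of bound gene ids.
#' @param me_states output of [me_state_classify()] (named by gene).
#' @param delta_me2 named log2(mutant/WT) mark change at C14.
#' @param expr_ratio_C14,expr_ratio_C14S1 named expression log2 ratios.
#' @param bounds group cut points (see [mark_change_groups()]).
#' @return list with `summary` (data.frame: class, n, r_C14, r_C14S1) and
#'   `lag_tests` (per-class data.frames from [lag_association_test()]).
#' @export
stratified_lag_analysis <- function(bound, me_states, delta_me2,
                                    expr_ratio_C14, expr_ratio_C14S1,
                                    bounds = c(0, 1)) {
  universe <- intersect(names(delta_me2), names(me_states))
  ids_bound <- intersect(universe, bound)
  classes <- c("me1-me3-", "me1+me3-", "me1-me3+", "me1+me3+")
  lag_tests <- list()
  rows <- lapply(classes, function(cl) {
    ids <- ids_bound[me_states[ids_bound] == cl]
    if (length(ids) < 3L) {
      lag_tests[[cl]] <<- NULL
      return(data.frame(class = cl, n = length(ids),
                        r_C14 = NA_real_, r_C14S1 = NA_real_))
    }
    grp <- mark_change_groups(delta_me2[ids], bounds)
    lag_tests[[cl]] <<- lag_association_test(grp, expr_ratio_C14,
                                             expr_ratio_C14S1)
    data.frame(class = cl, n = length(ids),
               r_C14 = safe_cor(delta_me2[ids], expr_ratio_C14[ids]),
               r_C14S1 = safe_cor(delta_me2[ids], expr_ratio_C14S1[ids]))
  })
  list(summary = do.call(rbind, rows), lag_tests = lag_tests)
}

safe_cor <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Per-gene mark change between two stages on the square-root-RPM scale
#'
#' Replicate-averaged RPM per stage, square-root transformed, differenced
#' (`stage_to` minus `stage_from`). Pair with [sqrt_pearson()] for
#' genotype-vs-genotype scatter statistics.
#'
#' @param cm a `count_matrix`.
#' @param assay assay name.
#' @param genotype `"WT"` or `"mutant"`.
#' @param stage_from,stage_to stage labels.
#' @return named numeric vector of per-gene sqrt-RPM differences.
#' @export
mark_stage_delta <- function(cm, assay, genotype, stage_from, stage_to) {
  from <- cm_mean_norm(cm, genotype, stage_from, assay, "RPM")
  to <- cm_mean_norm(cm, genotype, stage_to, assay, "RPM")
  sqrt(to) - sqrt(from)
}

#' Genes down-regulated in the mutant at one stage
#'
#' Paired count test of mutant versus WT RNA at the given stage; the set is
#' genes with BH q < `deg_p` and fold change < `deg_fc_down`.
#'
#' @param rna a `count_matrix` with RNA triplicates for both genotypes.
#' @param stage stage to compare at.
#' @param thresholds an [analysis_thresholds()] object.
#' @return list with `genes` and the per-gene `table`.
#' @export
down_in_mutant_set <- function(rna, stage = "C14S1",
                               thresholds = analysis_thresholds()) {
  res <- condition_test(rna, "RNA", "mutant", stage, "WT", stage)
  genes <- res$gene_id[res$q_value < thresholds$deg_p &
                         res$effect < thresholds$deg_fc_down]
  list(genes = genes, table = res)
}

#' Select primed target genes (four-set intersection)
#'
#' The candidate targets are genes that (1) gain the mark in the mutant
#' during the intermediate stage (hyper set), (2) are up-regulated upon
#' induction in WT, (3) are down-regulated in the mutant upon induction, and
#' (4) are TF-bound. Reports the full Venn cell cardinalities alongside.
#'
#' @param hyper_me2,ugs_s1,down_in_mutant_s1,bound character gene-id vectors.
#' @return list with `targets` (the intersection), `membership` (per-gene
#'   logical table over the union), and `venn` (pattern x count).
#' @export
select_primed_targets <- function(hyper_me2, ugs_s1, down_in_mutant_s1, bound) {
  sets <- list(hyper_me2 = hyper_me2, UGs_S1 = ugs_s1,
               down_in_mutant_S1 = down_in_mutant_s1, bound = bound)
  universe <- sort(unique(unlist(sets)))
  membership <- data.frame(gene_id = universe, stringsAsFactors = FALSE)
  for (nm in names(sets)) membership[[nm]] <- universe %in% sets[[nm]]
  targets <- universe[rowSums(as.matrix(membership[, -1, drop = FALSE])) == 4L]
  if (length(universe)) {
    pattern <- apply(membership[, -1, drop = FALSE], 1L, function(r) {
      paste(ifelse(r, "1", "0"), collapse = "")
    })
    venn <- as.data.frame(table(pattern), stringsAsFactors = FALSE)
    names(venn) <- c("pattern", "count")
  } else {
    venn <- data.frame(pattern = character(), count = integer())
  }
  list(targets = targets, membership = membership, venn = venn)
}

#' Relative-expression table for heat maps
#'
#' Normalizes RNA counts (RPM by default), adds the half-minimum pseudocount,
#' averages replicates per genotype x stage condition, divides every
#' condition by WT-C14 per gene, and z-scores the rows.
#'
#' @param rna a `count_matrix` with RNA for all stages and genotypes.
#' @param genes gene ids to include.
#' @param scale `"RPM"` or `"RPKM"`.
#' @return list with `zscores` and `relative` (pre-z-score) matrices,
#'   genes x conditions (columns named `genotype.stage`).
#' @export
relative_expression_table <- function(rna, genes, scale = c("RPM", "RPKM")) {
  scale <- match.arg(scale)
  missing <- setdiff(genes, rownames(rna$counts))
  if (length(missing)) {
    stop("genes absent from the count matrix: ",
         paste(missing, collapse = ", "))
  }
  sel <- cm_select(rna, assay = "RNA")
  norm <- if (scale == "RPM") {
    rpm(sel$counts, sel$samples$library_size)
  } else {
    rpkm(sel$counts, sel$unit_lengths, sel$samples$library_size)
  }
  norm <- add_half_min_pseudocount(norm)
  conds <- unique(sel$samples[, c("genotype", "stage")])
  cond_means <- sapply(seq_len(nrow(conds)), function(i) {
    cols <- sel$samples$genotype == conds$genotype[i] &
      sel$samples$stage == conds$stage[i]
    rowMeans(norm[, cols, drop = FALSE])
  })
  colnames(cond_means) <- paste(conds$genotype, conds$stage, sep = ".")
  cond_means <- cond_means[genes, , drop = FALSE]
  if (!"WT.C14" %in% colnames(cond_means)) stop("WT C14 condition is required")
  relative <- cond_means / cond_means[, "WT.C14"]
  list(zscores = zscore_rows(relative), relative = relative)
}

#' Expression summaries per mark-presence class
#'
#' Median and quartiles of log2 expression (pseudocounted) per class; classes
#' may be the four me1/me3 states or all eight me1/me2/me3 combinations.
#'
#' @param expr named per-gene expression values (RPKM).
#' @param classes named per-gene class labels; a factor's levels define the
#'   reported rows (empty classes give NA rows).
#' @return data.frame: `class`, `n`, `median`, `q25`, `q75` (log2 scale).
#' @export
expression_by_me_state <- function(expr, classes) {
  lev <- if (is.factor(classes)) levels(classes) else sort(unique(classes))
  expr <- add_half_min_pseudocount(expr[names(classes)])
  lx <- log2(expr)
  rows <- lapply(lev, function(cl) {
    v <- lx[classes == cl]
    if (length(v) == 0L) {
      return(data.frame(class = cl, n = 0L, median = NA_real_,
                        q25 = NA_real_, q75 = NA_real_))
    }
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(class = cl, n = length(v), median = q[2], q25 = q[1], q75 = q[3])
  })
  do.call(rbind, rows)
}
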