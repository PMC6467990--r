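test_that("stage-response sets respect the fold-change and q thresholds", {
  set.seed(51)
  n <- 300L
  base <- matrix(rpois(n * 3, 100), n)
  up <- base                                       # null genes: a = b exactly
  up[1:20, ] <- matrix(rpois(20 * 3, 300), 20)     # strong induction
  up[21:40, ] <- matrix(rpois(20 * 3, 30), 20)     # strong repression
  cm <- build_cm(list("WT.C14" = base, "WT.C14S1" = up, "WT.C14S7" = base))
  sets <- stage_response_sets(cm)
  ids <- rownames(cm$counts)
  expect_setequal(sets$UGs_S1, ids[1:20])
  expect_setequal(sets$DGs_S1, ids[21:40])
  expect_length(sets$UGs_S7, 0L)
  expect_length(sets$DGs_S7, 0L)
  expect_true(all(sets$tables$S1$q_value >= sets$tables$S1$p_value - 1e-12))
  # missing stage errors
  cm2 <- build_cm(list("WT.C14" = base, "WT.C14S1" = up))
  expect_error(stage_response_sets(cm2), "no samples match")
})

test_that("hyper-mark genes require both ratio > 1.5 and p < 0.01", {
  n <- 200L
  base <- matrix(1000L, n, 2)
  base[3, ] <- 2L      # keeps the half-minimum pseudocount small (1 RPM)
  mut <- base
  mut[1, ] <- 1600L    # ratio ~1.6, decisively significant at these counts
  mut[2, ] <- 1400L    # ratio ~1.4: significant but below the ratio cut
  cm <- build_cm(list("WT.C14" = base, "mutant.C14" = mut), assay = "H3K4me2",
                 libsize = 1e6)
  hy <- hyper_mark_genes(cm)
  ids <- rownames(cm$counts)
  expect_equal(hy$genes, ids[1])
  expect_lt(hy$table$p_value[2], 0.001)   # p alone would have called gene 2
  # identical genotypes: empty set
  cm0 <- build_cm(list("WT.C14" = base, "mutant.C14" = base),
                  assay = "H3K4me2")
  expect_length(hyper_mark_genes(cm0)$genes, 0L)
})

test_that("mark-change groups partition with closed middle interval", {
  d <- setNames(c(-0.5, 0.5, 1.5, 0, 1), paste0("g", 1:5))
  g <- mark_change_groups(d)
  expect_equal(unname(g), c("i", "ii", "iii", "ii", "ii"))
  expect_true(all(g %in% c("i", "ii", "iii")))
  expect_length(g, length(d))
})

test_that("lag association test is exact on small groups and NA below n = 2", {
  ids <- paste0("g", 1:5)
  groups <- setNames(rep("iii", 5), ids)
  r14 <- setNames(rep(0, 5), ids)
  rs1 <- setNames(rep(-1, 5), ids)
  res <- lag_association_test(groups, r14, rs1)
  iii <- res[res$group == "iii", ]
  expect_equal(iii$p_value, 2 / 32)
  expect_equal(iii$n, 5L)
  expect_true(is.na(res$p_value[res$group == "i"]))
  # identical ratios: p = 1
  res2 <- lag_association_test(groups, rs1, rs1)
  expect_equal(res2$p_value[res2$group == "iii"], 1)
})

test_that("me-state classification is strict at the threshold and partitions", {
  me1 <- setNames(c(25, 20, 5, 30), paste0("g", 1:4))
  me3 <- setNames(c(5, 25, 25, 30), paste0("g", 1:4))
  cl <- me_state_classify(me1, me3)
  expect_equal(unname(cl), c("me1+me3-", "me1-me3+", "me1-me3+", "me1+me3+"))
  expect_length(cl, 4L)
})

test_that("select_primed_targets computes the four-way intersection and Venn", {
  sel <- select_primed_targets(c("A", "B", "C"), c("B", "C"),
                               c("B", "C", "D"), "C")
  expect_equal(sel$targets, "C")
  expect_equal(sum(sel$venn$count), nrow(sel$membership))
  expect_length(select_primed_targets(character(), c("B"), c("B"), c("B"))$targets,
                0L)
})

test_that("down_in_mutant_set flags attenuated genes only", {
  set.seed(53)
  n <- 200L
  wt <- matrix(rpois(n * 3, 120), n)
  mut <- matrix(rpois(n * 3, 120), n)
  mut[1:15, ] <- matrix(rpois(15 * 3, 50), 15)
  cm <- build_cm(list("WT.C14S1" = wt, "mutant.C14S1" = mut))
  down <- down_in_mutant_set(cm, "C14S1")
  expect_setequal(down$genes, rownames(cm$counts)[1:15])
  cm0 <- build_cm(list("WT.C14S1" = wt, "mutant.C14S1" = wt))
  expect_length(down_in_mutant_set(cm0, "C14S1")$genes, 0L)
})

test_that("relative expression table self-normalizes to WT-C14", {
  counts <- list()
  for (g in c("WT", "mutant")) for (s in c("C0", "C14", "C14S1", "C14S7")) {
    counts[[paste(g, s, sep = ".")]] <- matrix(c(100L, 200L), 2, 2)
  }
  counts[["WT.C14S1"]] <- matrix(c(200L, 400L), 2, 2)
  cm <- build_cm(counts)
  rel <- relative_expression_table(cm, rownames(cm$counts))
  expect_equal(unname(rel$relative[, "WT.C14"]), c(1, 1))
  # libsize 1e6 makes RPM = count; smallest positive RPM is 100, so the
  # half-minimum pseudocount is 50: gene1 (200+50)/(100+50), gene2
  # (400+50)/(200+50)
  expect_equal(unname(rel$relative[, "WT.C14S1"]),
               c(250 / 150, 450 / 250), tolerance = 1e-12)
  expect_equal(unname(rowMeans(rel$zscores)), c(0, 0))
  expect_error(relative_expression_table(cm, "nope"), "nope")
})

test_that("expression summaries by me-state report all classes", {
  expr <- setNames(c(rep(8, 4), rep(64, 4)), paste0("g", 1:8))
  classes <- factor(setNames(c(rep("lo", 4), rep("hi", 3), "empty_never"),
                             names(expr))[names(expr)],
                    levels = c("lo", "hi", "empty_never", "absent"))
  out <- expression_by_me_state(expr, classes)
  expect_equal(out$n, c(4L, 3L, 1L, 0L))
  expect_true(is.na(out$median[4]))
  expect_gt(out$median[2], out$median[1])
  expect_equal(sum(out$n), length(expr))
})

test_that("mark_stage_delta is zero for identical stages and matches hand math", {
  m14 <- matrix(c(100L, 400L), 2, 2)
  m0 <- matrix(c(25L, 100L), 2, 2)
  cm <- build_cm(list("WT.C0" = m0, "WT.C14" = m14), assay = "H3K4me2",
                 libsize = 1e6)
  d <- mark_stage_delta(cm, "H3K4me2", "WT", "C0", "C14")
  expect_equal(unname(d), sqrt(c(100, 400)) - sqrt(c(25, 100)))
  d0 <- mark_stage_delta(cm, "H3K4me2", "WT", "C14", "C14")
  expect_equal(unname(d0), c(0, 0))
  expect_error(mark_stage_delta(cm, "H3K4me2", "WT", "C14", "C14S1"),
               "no samples match")
})
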