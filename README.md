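# primedchip

Detection of epigenetically **primed** genes in staged regeneration time
courses. Priming here means: a histone-mark change in an intermediate tissue
state (H3K4me2 removal in auxin-induced callus) that leaves **concurrent**
gene expression unchanged, but determines how strongly the gene responds when
a **later** stimulus (cytokinin-driven shoot induction) arrives. The package
is written for epigenomics groups analysing two-genotype (wild type vs
demethylase mutant), four-stage (C0, C14, C14S1, C14S7) ChIP-seq + RNA-seq
designs, and ships a synthetic-data generator that emulates such a study so
every stage of the analysis is testable without any sequencing data.

## What it computes

Given a gene annotation, per-sample aligned-read BED files (or count tables)
and a sample sheet, the pipeline:

1. **Counts reads per genic region** (gene body ± 2 kb), after extending each
   read from its 5′ end to the 250 bp mean insert size, with ≥ 1 bp overlap
   multi-assignment; draws metagene profiles (scaled gene body plus flank
   bins, orientation-normalized).
2. **Calls differential genes with a paired binomial–Stouffer test.** For
   replicate pair *k* with counts *a_k*, *b_k* and library sizes *A_k*,
   *B_k*, conditional on *n_k = a_k + b_k* the null is
   *a_k ~ Binomial(n_k, π_k)* with *π_k = A_k / (A_k + B_k)*; the one-sided
   upper p-value is mapped to *z_k = Φ⁻¹(1 − p_k)* and combined as
   *Z = Σ z_k / √K*, two-sided *p = 2 Φ(−|Z|)*. Effects are fold changes of
   pseudocounted (half of the minimum positive value) replicate-mean RPM.
   Stage-response sets use BH *q* < 0.01 with FC > 1.25 (UGs) or < 0.8 (DGs);
   hyper-mark genes use raw *p* < 0.01 with mutant/WT ratio > 1.5.
3. **Calls TF-bound genes** with a windowed local-Poisson enrichment test
   (500 bp windows, 250 bp step): the null expectation is the local lambda —
   the maximum of the library-scaled control count in the window, the scaled
   control count in a centred 10 kb span prorated to window width, and the
   genome-wide treatment rate — with genome-wide BH at *q* < 0.1, peak
   merging, and ≥ 1 bp peak-to-genic-region assignment.
4. **Runs the lag analysis**: genes are grouped by their log2(mutant/WT)
   H3K4me2 change at C14 (group i < 0, 0 ≤ ii ≤ 1, iii > 1); per group a
   paired Wilcoxon signed-rank test (exact by enumeration for small samples)
   compares the expression log2 ratios at C14 vs C14S1. Genes are stratified
   by H3K4me1/H3K4me3 presence (> 20 RPKM) and the Pearson correlation of
   mark change vs expression change is reported per stage and stratum.
5. **Selects primed targets**: the four-way intersection of hyper-H3K4me2
   genes, WT-upregulated-at-S1 genes, mutant-downregulated-at-S1 genes and
   TF-bound genes, with full Venn cardinalities.

## Worked example

```r
library(primedchip)

ds <- simulate_dataset(sim_config(seed = 1))   # 2000 genes, 10% primed

hy    <- hyper_mark_genes(ds$chip)                       # mutant/WT H3K4me2 at C14
treat <- extend_reads(ds$reads[["TF-ChIP_mutant_C14_r1"]], 250, ds$chrom_lengths)
ctrl  <- extend_reads(ds$reads[["TF-control_WT_C14_r1"]], 250, ds$chrom_lengths)
bound <- assign_bound_genes(
  call_peaks(window_enrichment(treat, ctrl, ds$chrom_lengths), 0.1), ds$regions)
sets  <- stage_response_sets(ds$rna)
down  <- down_in_mutant_set(ds$rna)
sel   <- select_primed_targets(hy$genes, sets$UGs_S1, down$genes, bound)

length(hy$genes); length(bound); length(sel$targets)
#> 196 / 601 / 194

dme2 <- genotype_log2_ratio(ds$chip, "H3K4me2", "C14")
e14  <- genotype_log2_ratio(ds$rna, "RNA", "C14")
es1  <- genotype_log2_ratio(ds$rna, "RNA", "C14S1")
cor(dme2, e14); cor(dme2, es1)
#> +0.019 / -0.717
lag_association_test(mark_change_groups(dme2), e14, es1)[, 1:5]
#>   group    n      W      p_value minus_log10_p
#> 1     i 1497 550416 5.416419e-01     0.2662877
#> 2    ii  477  89796 1.323285e-27    26.8783467
#> 3   iii   26    351 8.803670e-06     5.0553363
```

Reading the output: 196 genes gain H3K4me2 in the mutant callus, essentially
all of them TF-bound; 194 of the 200 truly primed genes survive the four-way
intersection. The mark change is uncorrelated with the expression change
*while still in callus* (r = +0.02 at C14) but strongly anti-correlated one
day after shoot induction (r = −0.72 at C14S1), and the genes with the
largest mark gain (group iii) show a significant C14-vs-C14S1 shift — the
stage-lagged priming signature.

The same analysis runs end to end from files via
`run_pipeline(list(outdir = "run1", seed = 1), "all")`, which writes count
tables, peak BEDs, gene sets, the lag-test tables, a JSON priming report and
a reproducibility manifest.

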