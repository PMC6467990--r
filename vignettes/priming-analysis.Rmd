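---
title: "Detecting stage-lagged chromatin priming: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting stage-lagged chromatin priming}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The analysis in one paragraph

Plant explants cultured on auxin-rich medium form callus; transfer to
cytokinin-rich medium induces shoots. A histone demethylase removes H3K4me2
over gene bodies during callus formation. In the demethylase mutant this
removal fails, yet expression of the affected genes in callus is unchanged —
the defect only becomes visible one day after shoot induction, when those
genes fail to activate. This package implements that *priming* analysis:
quantify the mark change in the intermediate state, show it is uncorrelated
with concurrent expression, show it predicts the later response, and select
the candidate target genes at the intersection of four evidence streams
(hyper-marked in the mutant, induced in wild type, attenuated in the mutant,
and bound by the demethylase).

## Data model and conventions

All intervals are 0-based half-open (BED convention); GFF3 input is shifted
on ingest. Counting units are *genic regions*: gene body plus 2 kb flanks,
clamped at chromosome ends. ChIP reads are extended from their fixed 5' end
to the 250 bp mean insert size before counting (reads longer than the target
are truncated from the 5' end, so every fragment has identical length — this
makes coverage totals exactly `fragments x 250` and keeps the extension
idempotent). A read overlapping k genic regions by at least 1 bp counts once
in each: the regions themselves overlap nowhere in the simulated genomes, and
multi-assignment is the natural semantics when they do.

Counts live in a `count_matrix`: an integer genes x samples matrix plus the
sample sheet (genotype in {WT, mutant}, stage in {C0, C14, C14S1, C14S7},
assay, replicate, library size) and per-gene unit lengths. Normalizations are
RPM (`1e6 * count / library_size`) and RPKM (additionally per kb of unit
length). Before any ratio or logarithm, half of the smallest strictly
positive value of the whole matrix at hand is added to every entry; the
offset is recorded in the result's `pseudocount` attribute. Ratios always
average replicates *after* pseudocounting, and tests always act on raw
per-replicate counts.

## The paired count test

Differential calls (stage responses, mutant attenuation, hyper-mark genes)
use one fully specified primitive rather than an external DE package. Per
replicate pair k, conditional on the total `n_k = a_k + b_k`, the count
`a_k` is binomial with null proportion `pi_k = A_k / (A_k + B_k)` given by
the two library sizes — the classical conditional test for comparing two
Poisson-like counts with known exposure ratio. The one-sided upper p-value
becomes a signed normal score `z_k = qnorm(1 - p_k)` (clamped to [-8, 8]
purely against floating-point under/overflow), scores are Stouffer-combined
`Z = sum(z_k) / sqrt(K)`, and the two-sided p is `2 * pnorm(-|Z|)`.
Replicates with `n_k = 0` carry no information and are dropped from the
combination; a gene with no informative replicate reports p = 1.

Properties worth knowing:

* The test is exact at small counts and calibrated whenever counts are
  (conditionally) binomial — multinomially placed ChIP reads satisfy this.
* RNA counts are simulated (and in reality behave) negative-binomially; a
  conditional binomial test is then mildly anti-conservative, increasingly so
  with dispersion. At the dispersion regime of tight biological replicates
  this is small, and all expression calls are protected by the joint
  threshold (BH q < 0.01 *and* fold change beyond 1.25 / 0.8).
* Because the one-sided tail includes the observed atom, Z sits slightly
  below zero under an exactly symmetric null — a discreteness quirk, not a
  bias in p.

Thresholds (defaults in `analysis_thresholds()`): differential expression
q < 0.01 with FC > 1.25 (up) or < 0.8 (down); hyper-mark raw p < 0.01 with
mutant/WT ratio > 1.5; binding q < 0.1; me-state presence strictly above
20 RPKM; mark-change group bounds 0 and 1 on the log2 scale. The group
boundaries leave Delta = 0 and Delta = 1 formally unassigned; with
pseudocounted ratios these are measure-zero and both are assigned to the
middle group so the three groups partition the universe.

## Wilcoxon signed-rank

The lag test per group is a paired Wilcoxon signed-rank across genes of the
expression log2 ratios at C14 versus C14S1. Zero differences are dropped,
absolute differences are midranked, and W is the rank sum of positive
differences. Tie-free samples up to n = 25 are tested exactly against the
signed-rank distribution with the symmetric two-sided rule
`min(1, 2 * min(P(W+ >= w), P(W+ <= w)))`; tied samples up to n = 15 are
tested exactly by direct enumeration of all 2^n sign assignments over the
midranks (small tied groups are common in the grouped lag analysis, and the
normal approximation is poor exactly there); everything else uses the normal
approximation with tie-corrected variance and a 0.5 continuity correction.
Groups with fewer than two genes report NA rather than erroring — on null
data the iii band (log2 change > 1) is typically empty, and NA is the honest
summary of "no genes reached the band".

## The binding caller

Bound genes are called from one treatment/control ChIP pair by a windowed
local-Poisson test (500 bp windows, 250 bp step). Fragments are assigned to
windows by their midpoints: window counts, the 10 kb-span prorated count and
the genome-rate floor then all scale identically with span width. (Counting
any overlap would inflate window counts by `(width + fragment)/width`
relative to the prorated floors, which systematically under-sets the null
expectation — measured on simulated data this admitted ~20% false bound
genes.) The local lambda is the maximum of the scaled control count in the
window, the scaled control count in a centred 10 kb span prorated to window
width, and the genome-wide treatment rate times width; the last floor guards
against zero-control windows on sparse toy genomes. Windows are BH-adjusted
genome-wide, significant windows merged when overlapping or book-ended, and
a gene is bound iff a peak overlaps its genic region by >= 1 bp.

## The synthetic-data generator

`sim_config()` defaults *are* the emulated study conditions: 2000 genes
(1–3 kb bodies, >= 5 kb gaps so 2 kb flanks never merge) on 5 chromosomes;
RNA in biological triplicate at all four stages for both genotypes; mark ChIP
(H3, H3K4me1/2/3) in duplicate at C0, C14, C14S1; one TF ChIP + control pair
at C14. Ground truth: 30% of genes TF-bound, 70% each H3K4me1/H3K4me3
positive (~49% of bound genes me1+me3+), 10% primed — drawn from the bound
me1+me3+ pool, mirroring where such targets concentrate; a further 10% are
down-regulated on induction in both genotypes so the down-response sets are
non-degenerate.

Effect structure: primed genes are induced 2x at C14S1/C14S7 in wild type
but only 2x0.5 in the mutant (the priming defect); the mutant carries a 2x
H3K4me2 excess on primed genes at C14 that is maintained at C14S1 (the mark
is removed during callus formation and not re-adjusted after induction).
Per-gene lognormal intrinsic factors (sdlog 0.5) for expression and for each
mark are shared across genotypes, stages and replicates — they create the
strong between-gene signal that makes genotype-vs-genotype sqrt-RPM scatters
correlate near 1 under the null, as deep ChIP replicates do. H3K4me2
additionally carries a gene-specific C0/C14 ratio (lognormal around 0.7) so
callus formation changes the mark differentially across genes.

RNA counts are negative-binomial with a single shared dispersion of 0.005
(biological-coefficient-of-variation ~7%, appropriate for pooled isogenic
callus replicates); the recorded RNA library size is the *mapped* depth
(twice the expected counted total, with ~5% per-sample lognormal depth
variation that scales all per-gene means consistently). Defining the library
as the counted column total would make per-million ratios of null genes
inherit a ~12% compositional shift from the induced genes at S1 — the bias
TMM-style normalization corrects in real analyses and which is out of scope
here; normalizing against mapped depth is what per-million-mapped-reads
means and keeps null genes null.

ChIP reads are emitted at 175 bp (so the 250 bp extension step is genuinely
exercised), placed uniformly within gene bodies at fixed per-bp densities:
0.02 for a present mark, 0.001 for an absent one, TF background 0.05
genome-wide with 4x body enrichment on bound genes, 75% of the enrichment
reads in the 3' half of the body (strand-aware). At the 2000-gene scale these
densities put present marks near 115 RPKM and absent marks near 6 RPKM,
cleanly straddling the 20 RPKM presence cut. RPKM is composition-relative,
so this calibration holds at the study scale; reduced-size simulations used
in unit tests do not exercise the me-state threshold.

What the generator does **not** emulate: mappability/GC bias, duplicate
reads, batch effects, gene-length-dependent expression bias, peak shape
beyond the 3' skew, TMM-scale compositional artefacts, or the genome-scale
gene counts of a real organism. Passing recovery tests therefore demonstrate
correctness of the statistical machinery under the declared generative
model, not performance on arbitrary real libraries.

## Numerical and degenerate-input choices

* Metagene binning: body rescaled to 100 bins, each 2 kb flank to 50 (the
  flank width is fixed by the analysis; bin counts follow common
  metagene-profiler defaults). Bodies shorter than the bin count are mapped
  onto the grid by per-base linear interpolation — deterministic handling of
  a case the counting rules never define. Minus-strand genes are reversed
  before averaging so bins run 5' to 3'.
* Flank clamping at position 0 and at chromosome ends is applied before
  counting.
* Row z-scores use the population (divisor-n) standard deviation; constant
  rows map to zero.
* An all-zero matrix has no defined half-minimum pseudocount and errors.
* The relative-expression heat-map table normalizes per-million values by
  default (`scale = "RPM"`, matching how such heat maps are usually
  displayed) with `"RPKM"` available, pseudocounts first, averages
  replicates, divides by WT-C14 and z-scores rows.
* The run manifest records the config, input checksums and package version
  but deliberately no wall-clock timestamp, so identical runs are
  byte-identical; timestamps go to the stderr log.
* An optional per-gene H3 normalization of methylation ratios is *not*
  applied by default: H3 is analysed as its own assay, and the genotype
  ratios shown throughout are mark/mark.

## Problem sizes

The shipped test-suite runs the full study scale (2000 genes) for the
recovery, priming-signature and calibration suites (20 simulated null
datasets restricted to the assays those suites consume), and reduced scales
(200–500 genes) for unit tests of the plumbing; the end-to-end determinism
check runs the complete pipeline twice at 400 genes. `scripts/acceptance.R`
recomputes everything at the study scale from one seed.

## Known limitations

* The paired binomial test is not a dispersion-aware DE method; with noisy
  biological replicates it will over-call unless the fold-change thresholds
  do their share of the filtering.
* Library-size choice (mapped vs counted) is left to the sample sheet for
  real data; the two differ exactly when composition shifts, which is also
  when the analysis is most delicate.
* The binding caller has no fragment-size estimation, summit refinement or
  duplicate filtering; it is designed for the gene-level bound/unbound
  decision that the downstream analysis consumes.
* Four-set target selection applies no expression floor; very low-expressed
  genes can enter through noisy ratios if thresholds are relaxed.
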