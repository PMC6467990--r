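Package: primedchip
Title: Stage-Lagged Chromatin Priming Analysis for ChIP-seq and RNA-seq Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects epigenetically "primed" genes in staged tissue-culture
    time courses: genes whose histone-mark change in an intermediate state
    (e.g. H3K4me2 removal in callus) leaves concurrent expression unchanged
    but alters the expression response at a later induction stage. Provides
    genic-region read counting and metagene profiles from BED intervals,
    RPM/RPKM normalization with half-minimum pseudocounts, a paired
    binomial-Stouffer count test, exact and approximate Wilcoxon signed-rank
    tests, a windowed local-Poisson enrichment caller for transcription-factor
    binding, stage-response and hyper-mark gene-set construction, me-state
    stratified lag analysis, primed-target selection, and a negative-binomial
    synthetic-data generator emulating a two-genotype, four-stage regeneration
    study design.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    pracma
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
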