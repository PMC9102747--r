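Package: lockscape
Title: Repressive Chromatin Domain and Enhancer Landscape Analysis for
    Hematopoietic Differentiation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-mark ChIP-seq, RNA-seq and CpG
    methylation profiles of hematopoietic cell types. Implements calling of
    large organized chromatin K27/K9-modification domains (LOCKs) from broad
    H3K27me3 enriched regions and their contraction statistics, a pairwise
    GC-corrected differential-expression method with quantile-wise Gaussian
    fold-change nulls (DEfine), promoter density profiling, a thresholded
    enhancer catalogue with active/primed states and rank-curve
    super-enhancers, a motif enrichment score over enhancer signal, and a
    seeded synthetic cohort generator with a ground-truth ledger for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    IRanges,
    limma
Config/testthat/edition: 3
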