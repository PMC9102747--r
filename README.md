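# lockscape

Repressive chromatin domains and enhancer landscapes across hematopoietic
differentiation, as a tested R pipeline.

Reference epigenomes of human cord-blood populations show that the four
CD34+ progenitor subsets (CD34+CD38−, CMP, GMP, MEP) share large organized
chromatin K27-modification domains (**LOCKs**: contiguous multi-peak
stretches of H3K27me3 ≥ 100 Kb, co-marked by H3K9me3 and lying in
lamina-associated domains), which are retained by mature B and T cells but
contract to a punctate profile in monocytes and erythroblasts — with
matching changes in gene-body H3K27me3, CpG methylation, enhancer states and
super-enhancers. `lockscape` implements the bespoke computations behind such
an analysis for anyone who has peak calls, tag tracks, expression tables and
methylation calls and wants the downstream statistics reproducible:

* **DEfine** — pairwise differential expression for count/RPKM data without
  replicates. Assuming ~90% of genes unchanged, RPKM is renormalized in 10
  GC bins so the mode of log2 fold-change is GC independent (the correction
  for bin *b* is `2^mode_b`, driving every per-bin mode to 0); then for each
  mean-expression quantile *q* a Gaussian null `N(mu_q, sigma_q)` is fitted
  to the trimmed log2 fold-changes, `z = (lfc − mu_q)/sigma_q` gives
  two-sided p-values and Benjamini–Hochberg control calls genes at
  `q ≤ 0.001`.
* **LOCK calling** — peaks < 1 Kb dropped; peaks stitched when the inter-peak
  gap is ≤ `exp(median + 1.5·IQR)` of chromosome-wise log gaps; clusters
  with ≥ 2 peaks kept; spans < 100 Kb eliminated. Plus retention/loss across
  cell types (reciprocal overlap ≥ 25%), within-domain segment-width
  contraction, LAD overlap, H3K9me3 co-occupancy inside vs outside domains
  and CpG methylation contrasts (Welch t-tests).
* **Promoter profiling** — normalized densities at TSS ± 2 Kb (tags per Kb
  per 10M enriched-region tags), Spearman correlation with average-linkage
  clustering, Kolmogorov–Smirnov tests on fragment position distributions,
  and the gene-body rule: a gene is H3K27me3-marked when > 20% of its body
  is covered.
* **Enhancer catalogue** — union of H3K27ac enriched regions minus TSS ± 2 Kb
  windows; libraries subsampled to the lowest depth (binomial thinning);
  regions need > 40 raw tags in ≥ 1 cell type; tag densities are quantile
  normalized per cell type; *active* means normalized H3K27ac signal > 25,
  *primed* means not active with H3K4me1 signal > 40. Gains/losses and
  provenance vs the CD34+CD38− compartment, nearest-promoter association
  (≤ 50 Kb), and rank-curve super-enhancers: stitch within 12.5 Kb, rank by
  total signal, cut where the curve scaled to the unit square has slope 1.
* **Motif scores** — per motif, the cumulative quantile-normalized H3K27ac
  signal over its regions is standardized across cell types and the
  reference's standard score subtracted; motifs for TFs < 1 RPKM everywhere
  are eliminated.
* **Synthetic cohort** — a seeded 8-cell-type generator (3 × 30 Mb genome)
  that plants all of the above structure with a ground-truth ledger, so
  every stage is testable without controlled-access data.

## Worked example

```r
library(lockscape)

# a synthetic cohort with planted truth
cohort <- simulate_cohort(cohort_spec(seed = 7))

# DEfine on the canonical benchmark: 10,000 genes, 200 planted 4-fold effects
bench <- simulate_counts(n_genes = 10000, n_de = 200, de_lfc = 2, seed = 11)
res <- define_de(bench$table, "A", "B", fdr = 0.001)
called <- res[call != "ns", gene_id]
mean(bench$truth$gene_id %in% called)          # sensitivity: 0.995
1 - mean(called %in% bench$truth$gene_id)      # empirical FDP: 0.029

# LOCKs and the myeloid contraction
called_locks <- lapply(cohort$marks, function(m) call_locks(m$H3K27me3$regions))
sapply(called_locks[c("CMP", "Monocyte")], nrow) # 40 progenitor, 12 myeloid
prog <- locks_intersection(called_locks[c("CD34_38neg", "CMP", "GMP", "MEP")])
cmp <- compare_locks(prog, called_locks[c("Monocyte", "Erythroblast")])
cmp$summary$lost / cmp$summary$n_reference      # loss fraction 0.70, planted 0.70
```

The numbers printed above are what these calls produce on this seed: DEfine
recovers 199/200 planted 4-fold genes with 6 false calls, progenitors carry
40 LOCKs of which monocytes/erythroblasts retain 12, and the enriched
segments inside retained domains shrink from ~23.5 Kb to ~4.9 Kb
(`contraction_stats`), a ratio of 0.21 against the planted shrink factor
0.2.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default cohort under the given seed and re-runs the whole
pipeline from scratch — differential expression (plus the 10,000-gene
benchmark), LOCK calling with contraction/LAD/methylation statistics, the
enhancer catalogue with states, super-enhancers and gene association, and
motif scoring — logging a summary of each stage and writing the result JSON
to `--out`.
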