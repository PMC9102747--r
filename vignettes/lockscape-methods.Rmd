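---
title: "Methods: repressive domains, enhancer states and their synthetic test bed"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repressive domains, enhancer states and their synthetic test bed}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its methods: the models and
rules it implements, the tunable parameters and their defaults, what the
synthetic cohort does and does not emulate, and the numerical choices made
where the design was genuinely open. It states no empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## 1. Coordinates and interval algebra

All regions use 0-based half-open coordinates (BED convention); wiggle input
is converted on read, and chromosome dialects (`1` vs `chr1`) are normalized
to `chr*`. Sorting ties break lexicographically on (chrom, start, end, id).
`merge_intervals(x, max_gap)` joins intervals whose gap is at most `max_gap`
bp; book-ended intervals (gap 0) join at `max_gap = 0`. Tag tracks are
fixed-width bin vectors; the tag count of an arbitrary region pro-rates
boundary bins by overlap fraction, which makes region counts exact linear
functionals of the bin vector and lets a per-base oracle verify them to
1e-9. ChIP-seq densities are normalized to the total number of tags inside
the cell type's enriched regions — not raw library depth — in units of tags
per Kb per 10 million enriched tags (the density unit is not fixed by
convention; this choice is documented here and used consistently).

## 2. Pairwise differential expression (DEfine)

The method is pairwise and replicate-free, resting on the heuristic that
~90% of genes do not change between two libraries.

1. **GC renormalization.** Genes expressed above 0.1 RPKM in at least one
   sample are split into 10 GC bins (quantile bins over GC fraction; bins
   under 50 genes merge into a neighbour with a warning). Within each bin
   the mode of `log2(RPKM_a / RPKM_b)` is estimated by a Gaussian-kernel
   density (Silverman's bandwidth, argmax on a 512-point grid) and sample b
   is multiplied by `2^mode` so every bin's mode moves to the global target
   mode, taken to be 0. Both the mode estimator and the target are open
   choices: the KDE is the least committal estimator of "the mode of the
   distributions", and target 0 encodes "most genes unchanged" directly.
2. **Quantile-wise Gaussian null.** Genes are binned into 10 quantiles of
   mean expression; per bin, points beyond median ± 3 MAD are trimmed
   ("removing extreme outliers" — the exact rule is an open choice) and a
   Gaussian `N(mu_q, sigma_q)` fitted by moments of the retained points. A
   zero-variance bin is an error naming the bin. Fits use robust moments
   after trimming rather than histogram least squares — another open choice,
   taken because it is deterministic and has no binning parameter.
3. **Calls.** `z = (lfc − mu_q)/sigma_q`, two-sided Gaussian p-values,
   Benjamini–Hochberg q-values (the generic "FDR control process"), calls at
   `q ≤ 0.001`. Zero counts are cushioned with a pseudocount of 0.5 reads
   converted to RPKM units. If more than half the genes are called, a
   warning flags that the ~90%-null heuristic is violated.

Consequences worth knowing: with pseudocounts the sample-swap symmetry is
exact only asymptotically (low-expression genes can flip near the
threshold), and after RPKM normalization the *global* fold-change mode sits
at the realized depth-ratio offset — the GC correction removes it along with
the GC trend, which is why per-bin modes are compared against 0 only after
correction.

## 3. LOCK calling and contraction

Broad-peak callers emit H3K27me3 enriched regions; domains are built from
them with parameters `WScutoff = 1.5`, `MinLength = 1000`, `peakNumMin = 2`
and a final 100 Kb span filter. Published peak-clustering tools for this step do
not document an internal window rule precisely enough to re-derive, so this
package uses an explicit rule with the conventional parameter semantics: peaks shorter than `MinLength`
are dropped; on each chromosome the stitching threshold is
`G = exp(median + WScutoff · IQR)` of the log inter-peak gaps (dispersion
multiplier on a robust scale); consecutive peaks with gap ≤ G form a
cluster; clusters need ≥ `peakNumMin` peaks and a span ≥ 100 Kb.
Chromosomes with fewer than three peaks fall back to the genome-wide
threshold, and the comparison is done in log space with a 1e-9 tolerance so
a gap exactly at the threshold stitches. The rule is deliberately simple
and is validated by parameter recovery on the synthetic cohort, not by
equivalence with the original tool. A known fragility is inherited by any
quantile-of-a-mixture rule: if background gaps ever outnumber one quarter
of a chromosome's gaps, the IQR inflates and over-stitching follows — the
generator's geometry keeps the intra-domain gap population dominant, and
real data with very sparse domains would deserve a per-chromosome sanity
check of `G`.

Cross-cell-type identity uses reciprocal overlap ≥ 25% (overlap needs a
threshold to be an equivalence; 25% is this package's documented choice). "Domains shared by all progenitors" is the bp-wise intersection of
the merged per-cell-type domain sets with the 100 Kb filter re-applied.
Contraction is quantified by the widths of contiguous enriched segments
inside domains; group contrasts are Welch t-tests on log widths
(Welch avoids the equal-variance assumption).
A region counts as inside domains for the H3K9me3 co-occupancy contrast
when more than half its bases are; occupancy is compared on log10(bp + 1).
LAD overlap counts a domain as overlapping at ≥ 1 bp and reports the
bp-level fraction alongside.

## 4. Promoters and gene bodies

Promoter windows are TSS ± 2 Kb, strand oriented (upstream = negative
offsets; orientation is this package's documented convention). The gene × cell-type density matrix uses the normalized density of
section 1; profile vectors are max-normalized (an all-zero profile stays
zero; ties leave the leftmost maximum at 1). Correlation matrices are
Spearman over genes with non-zero density in at least one cell type (to
avoid tied-zero inflation), clustered by average linkage on 1 − R. A gene is
H3K27me3-marked when strictly more than 20% of its body is covered by
enriched regions; retention/loss flows consider only genes marked in the
reference cell type, and the loss/upregulation overlap is
`|lost ∩ up| / |up| × 100` (reported as 0 with n = 0 when nothing is
upregulated).

## 5. Enhancer catalogue, states and super-enhancers

The catalogue is the merged union of all cell types' H3K27ac enriched
regions, minus any region overlapping a protein-coding TSS ± 2 Kb window.
Subsampling every H3K27ac library to the lowest depth is implemented as
binomial thinning of per-region tag counts with a fixed seed — read-level
subsampling is out of scope and thinning has the same first two moments. A
region must exceed 40 raw (post-thinning) tags in at least one cell type,
strictly. Signals are tag densities per Kb, quantile normalized across
regions within each cell type (columns mapped onto the mean of sorted
columns, ties averaged; rank order per column is preserved). Active means
signal > 25, primed means H3K4me1 signal > 40 and not active; states are
exclusive and "total enhancers" is active + primed.

Quantile normalization across cell types with *unequal* state composition
blurs near-threshold membership: a column with fewer truly-high regions
borrows reference values from columns with more, so counts of the
*secondary* (primed) state are only approximately recoverable. The
synthetic generator therefore equalizes the number of active regions per
cell type (a "constitutive" class active everywhere) — making active-state
recovery exact — while primed counts are asserted only within tolerance.

Super-enhancers follow the rank-curve recipe: TSS-proximal peaks removed,
remaining regions stitched within 12.5 Kb, stitched regions ranked by total
tag count, the curve scaled to the unit square, and the cutoff placed at
the tangent point of slope 1, i.e. the rank minimizing `y − x` (ties take
the middle index, so a perfectly linear ramp cuts at the curve midpoint and
is flagged degenerate, as is any tie set above 10% of points). The stitch
gap and TSS exclusion are this package's defaults — the recipe itself is
standard but fixes no parameter values. The cutoff is
scale-invariant by construction. On convex tails the tangent can admit the
one or two highest singleton regions in addition to planted high-amplitude
clusters; recovery assertions therefore check that every planted cluster is
called, not that nothing else ever is.

Gene association takes the nearest protein-coding TSS per region, drops
associations beyond 50 Kb, and breaks exact distance ties toward the
lexicographically smaller gene id (determinism). Methylation at a chosen
enhancer class pools per-CpG fractions per cell type (Welch t-test between
groups); the paired expression contrast over associated genes uses the
Wilcoxon signed-rank test.

## 6. Motif enrichment scores

Motif occurrences are an input (upstream PWM scanning in 300-bp windows is
out of scope). Motifs whose TF stays below 1 RPKM in every cell type are
eliminated (strictly below; 1.0 survives). Per motif, the cumulative
quantile-normalized H3K27ac signal over its region set (a set — duplicates
collapse) is computed per cell type; the "standard score" is the z-score of
that row across cell types (standardizing across cell types rather than
across motifs is the adopted convention and gives the antisymmetry
`score(A vs ref) = −score(ref vs A)`), and the enrichment score subtracts
the reference cell type's z. The significance screen is implemented
as a per-motif region-level Wilcoxon rank-sum test of the cell type's
signals against the reference's, BH-corrected, flagged at q < 0.05.

## 7. The synthetic cohort: what it emulates, and what it does not

The generator's defaults are the stated world: 8 cell types (4 progenitor,
2 myeloid, 2 lymphoid) on 3 × 30 Mb; 40 domains with log-normal widths
(median 300 Kb, log-sd 0.35); myeloid cells lose 70% of domains and shrink
the enriched segments of retained ones to 0.2 of their width; H3K9me3 tiles
~70% and the LAD annotation ~65% of domain bases; 8,000 genes with Beta-
distributed GC in [0.3, 0.75]; negative binomial counts (size 100) with a
monotone per-sample GC bias `exp(amp_s (gc − 0.5))`, amplitudes spread over
±1, and 300 planted effects per contrast with |log2 FC| in [1, 3] — for
myeloid contrasts 40% of upregulated genes are drawn from genes losing
gene-body H3K27me3, wiring the loss/upregulation overlap. CpG methylation
has a Beta(mean 0.75) baseline, sd-0.03 noise, a planted 0.2 depression in
myeloid cells inside retained-domain footprints and a 0.3 depression in
mature cells at enhancers that are progenitor-primed/mature-active.
Auto-planted DE benchmarks put effects on genes with baseline mean ≥ 150
counts — an effect planted on a gene with a handful of reads is noise, not
an effect — and that floor, like the dispersion, was set from power
considerations before any test was run.

Geometry is engineered so the stated statistical rules are *identifiable*:

* Broad cell types tile domains with ~U(20, 30) Kb segments and ~U(5, 10) Kb
  gaps; myeloid retained domains shrink segments left-anchored, giving gaps
  of ~21–34 Kb, and the punctate remnants outside retained domains are
  emitted as pairs ~25 Kb apart on domain-retaining chromosomes — so the
  chromosome-wise log-gap statistic stays anchored in the intra-domain
  range while a pair's < 100 Kb span can never be called a domain.
* Enhancer classes are placed ≥ 15 Kb apart (super-enhancer cluster members
  5–10 Kb apart inside ~50 Kb blocks), with active densities (90–180
  tags/Kb, clusters 250–450) far above and inactive densities far below the
  thresholds, a 5% borderline stratum near them, 20 constitutive actives
  equalizing per-column counts, 30 never-eligible regions and 50 decoys
  deliberately straddling TSS. Enhancers are laid out before genes; genes
  are then placed so no TSS window touches an enhancer.
* One pseudo-random stream per output family (named sub-seeds of the master
  seed) keeps one family's files stable when another family's parameters
  change; the same seed reproduces every file byte-identically.

What a green test does **not** establish: the generator has no read-level
noise, mappability or blacklist structure, no copy-number or GC-dependence
in ChIP tracks, no isoform structure (one TSS per gene), no biological
replicates, and peak boundaries are exact rather than caller-estimated. The
recovery results certify that the implementations compute the stated rules
correctly on data satisfying their assumptions — not that those rules are
robust to everything real libraries do.

## 8. Degenerate inputs and numerical conventions

Empty region sets error in methylation pooling and are propagated as empty
results elsewhere; a catalogue with no region past the tag floor errors; a
single-cell-type catalogue cannot be standardized for motif scores and
errors; constant log fold-changes produce the named zero-variance error;
the super-enhancer cutoff on one region or a flat curve is flagged
degenerate rather than guessed. The field-standard thresholds used throughout
(> 40 tags, > 25 and > 40 signal, > 20% coverage, < 1 RPKM, ≤ 50 Kb,
≥ 100 Kb) are all strict in the stated direction, and boundary cases are
unit-tested (40 tags is out, 41 in; signal 25 is not active; 1.0 RPKM
survives; 49 Kb kept, 51 Kb dropped).
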