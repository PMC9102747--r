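#!/usr/bin/env Rscript
# Step 4: promoter profiling and the gene-level H3K27me3 retention analysis.
#
# Normalized H3K27me3 and H3K4me3 densities at TSS +/- 2 Kb of protein-coding
# genes feed pairwise Spearman correlation with average-linkage clustering;
# gene bodies covered > 20% by H3K27me3 define marked genes, whose
# retention/loss versus CD34+CD38- is intersected with the upregulated genes
# of step 2.

suppressPackageStartupMessages({
  library(data.table)
  library(lockscape)
})

seed <- 7
dir.create("results", showWarnings = FALSE)
cohort <- simulate_cohort(cohort_spec(seed = seed))
cts <- cohort$cell_types$name
prog <- cohort$cell_types[class == "progenitor", name]

for (mark in c("H3K27me3", "H3K4me3")) {
  tracks <- lapply(cohort$marks, function(m) m[[mark]]$track)
  totals <- vapply(cts, function(ct) {
    enriched_tag_total(tracks[[ct]], cohort$marks[[ct]][[mark]]$regions)
  }, numeric(1))
  pm <- promoter_density_matrix(tracks, cohort$genes, totals)
  fwrite(as.data.table(pm, keep.rownames = "gene_id"),
         sprintf("results/04_promoter_density_%s.tsv", mark), sep = "\t")
  cc <- correlation_cluster(pm)
  fwrite(as.data.table(cc$R, keep.rownames = "cell_type"),
         sprintf("results/04_spearman_%s.tsv", mark), sep = "\t")
  pp <- mean(cc$R[prog, prog][upper.tri(diag(4))])
  pm_r <- mean(cc$R[prog, c("Monocyte", "Erythroblast")])
  message(sprintf("%s: mean progenitor-progenitor R = %.2f, progenitor-myeloid R = %.2f; order: %s",
                  mark, pp, pm_r, paste(cc$order, collapse = " ")))
}

# gene-body mark states and the Sankey flow vs the reference
k27 <- lapply(cohort$marks, function(m) m$H3K27me3$regions)
gm <- gene_mark_states(k27, cohort$genes, cohort$reference)
fwrite(gm$flows, "results/04_mark_flows.tsv", sep = "\t")
print(gm$flows)

# overlap of mark loss with upregulation (vs reference)
rows <- list()
for (ct in setdiff(cts, cohort$reference)) {
  de <- define_de(cohort$expression, ct, cohort$reference, fdr = 0.001)
  ov <- loss_upregulation_overlap(gm$lost_genes[[ct]], de)
  rows[[ct]] <- data.table(cell_type = ct, percent = ov$percent,
                           count = ov$count, n_up = ov$n_upregulated)
}
ov <- rbindlist(rows)
fwrite(ov, "results/04_loss_upregulation.tsv", sep = "\t")
print(ov)
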