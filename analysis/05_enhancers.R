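#!/usr/bin/env Rscript
# Step 5: enhancer catalogue, states, gains/losses, provenance,
# super-enhancers and methylation at mature-active enhancers.

suppressPackageStartupMessages({
  library(data.table)
  library(lockscape)
})

seed <- 7
dir.create("results", showWarnings = FALSE)
cohort <- simulate_cohort(cohort_spec(seed = seed))
cts <- cohort$cell_types$name
prog <- cohort$cell_types[class == "progenitor", name]
mature <- setdiff(cts, prog)
ref <- cohort$reference

catalogue <- build_catalogue(
  lapply(cohort$marks, function(m) m$H3K27ac$regions),
  lapply(cohort$marks, function(m) m$H3K27ac$track),
  cohort$genes,
  k4me1_tracks = lapply(cohort$marks, function(m) m$H3K4me1$track),
  seed = seed)
states <- classify_states(catalogue)

out <- cbind(catalogue$regions,
             as.data.table(catalogue$tags)[, lapply(.SD, round, 1)] |>
               setnames(paste0("tags.", cts)),
             as.data.table(round(catalogue$signal, 2)) |>
               setnames(paste0("signal.", cts)),
             as.data.table(states) |> setnames(paste0("state.", cts)))
fwrite(out, "results/05_enhancer_catalogue.tsv", sep = "\t")
print(attr(states, "counts"))

gl <- trace_gain_loss(states, ref)
fwrite(gl, "results/05_gain_loss.tsv", sep = "\t")
print(gl)

prov <- rbindlist(lapply(mature, function(m) {
  p <- provenance_fraction(states, m, ref, setdiff(prog, ref))
  data.table(cell_type = m, in_reference = p$in_reference,
             in_progenitors = p$in_progenitors, unique = p$unique, n = p$n)
}))
fwrite(prov, "results/05_provenance.tsv", sep = "\t")
print(prov)

se_rows <- list()
for (ct in cts) {
  se <- call_super_enhancers(cohort$marks[[ct]]$H3K27ac$regions,
                             cohort$marks[[ct]]$H3K27ac$track, cohort$genes)
  sup <- se[super == TRUE]
  write_bed(copy(sup)[, .(chrom, start, end, id = sprintf("SE_%02d", .I),
                          score = rank)],
            sprintf("results/05_superenhancers_%s.bed", ct))
  frac <- if (ct %in% mature) {
    specific_active_in_se(catalogue, states, se, ct, setdiff(cts, ct))$fraction
  } else NA_real_
  se_rows[[ct]] <- data.table(cell_type = ct, n_super = nrow(sup),
                              specific_active_in_se = frac)
}
se_summary <- rbindlist(se_rows)
fwrite(se_summary, "results/05_superenhancer_summary.tsv", sep = "\t")
print(se_summary)
message(sprintf("Super-enhancers: mature mean %.1f vs progenitor mean %.1f",
                se_summary[cell_type %in% mature, mean(n_super)],
                se_summary[cell_type %in% prog, mean(n_super)]))

# enhancer-gene association and the methylation/expression coupling at
# enhancers that are primed in progenitors and active in mature cells
assoc <- associate_genes(catalogue, cohort$genes)
fwrite(assoc, "results/05_enhancer_genes.tsv", sep = "\t")

mono_active <- rownames(states)[states[, "Monocyte"] == "active" &
                                  states[, ref] == "primed"]
me <- methylation_at_enhancers(cohort$methyl, catalogue, mono_active,
                               group_a = prog, group_b = "Monocyte")
message(sprintf("CpG methylation at monocyte-active/progenitor-primed enhancers: progenitors - monocyte = %.3f (p = %.2g)",
                me$delta_mean, me$test$p.value))
genes_assoc <- assoc[region_id %in% mono_active, gene_id]
wt <- paired_expression_test(cohort$expression, genes_assoc, "Monocyte", ref)
message(sprintf("Associated-gene expression monocyte vs %s: Wilcoxon signed-rank p = %.2g",
                ref, wt$p.value))
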