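#!/usr/bin/env Rscript
# Step 3: LOCK calling and the repressive-domain contraction analysis.
#
# H3K27me3 enriched regions are clustered into LOCKs (gap threshold
# exp(median + 1.5 IQR) of chromosome-wise log inter-peak gaps, >= 2 peaks,
# >= 100 Kb span). The progenitor consensus (bp-wise intersection of the 4
# progenitor LOCK sets) is compared against each mature cell type;
# within-domain enriched-segment widths quantify the broad-to-punctate
# contraction; LAD overlap, H3K9me3 co-occupancy and CpG methylation inside
# retained domains complete the picture.

suppressPackageStartupMessages({
  library(data.table)
  library(lockscape)
})

seed <- 7
dir.create("results", showWarnings = FALSE)
cohort <- simulate_cohort(cohort_spec(seed = seed))
prog <- cohort$cell_types[class == "progenitor", name]
mature <- setdiff(cohort$cell_types$name, prog)

called <- lapply(cohort$marks, function(m) call_locks(m$H3K27me3$regions))
for (ct in names(called)) {
  out <- copy(called[[ct]])[, .(chrom, start, end, id = lock_id, score = n_peaks)]
  write_bed(out, sprintf("results/03_locks_%s.bed", ct))
}
counts <- data.table(cell_type = names(called),
                     n_locks = vapply(called, nrow, 1L),
                     lock_bp = vapply(called, total_bp, 1))
print(counts)
fwrite(counts, "results/03_lock_counts.tsv", sep = "\t")

# retention/loss vs the progenitor consensus
consensus <- locks_intersection(called[prog])
cmp <- compare_locks(consensus, called[mature])
fwrite(cmp$summary, "results/03_lock_comparison.tsv", sep = "\t")
print(cmp$summary)
message(sprintf("Myeloid LOCK loss fraction: %.2f (planted %.2f)",
                mean(cmp$summary[target %in% c("Monocyte", "Erythroblast"),
                                 lost / n_reference]),
                cohort$spec$myeloid_loss))

# contraction of enriched segments within myeloid-retained domains
retained <- cohort$truth$locks[retained_myeloid == TRUE]
cs <- contraction_stats(retained,
                        lapply(cohort$marks[c("GMP", "MEP", "Monocyte", "Erythroblast")],
                               function(m) m$H3K27me3$regions))
fwrite(cs$summary, "results/03_contraction.tsv", sep = "\t")
tt <- segment_width_test(cs$segments[cell_type %in% c("GMP", "MEP"), width],
                         cs$segments[cell_type %in% c("Monocyte", "Erythroblast"), width])
message(sprintf("Mean segment width %0.f bp (progenitor) vs %0.f bp (myeloid), t-test p = %.2g",
                cs$summary[cell_type %in% c("GMP", "MEP"), mean(mean_segment_width)],
                cs$summary[cell_type %in% c("Monocyte", "Erythroblast"), mean(mean_segment_width)],
                tt$p.value))

# LAD association and H3K9me3 co-occupancy
lads <- rbindlist(lapply(names(called), function(ct) {
  lo <- lad_overlap(called[[ct]], cohort$lads)
  data.table(cell_type = ct, lock_frac = lo$lock_frac, bp_frac = lo$bp_frac)
}))
fwrite(lads, "results/03_lad_overlap.tsv", sep = "\t")
print(lads)

coq <- co_occupancy(called$CMP, cohort$marks$CMP$H3K9me3$regions,
                    cohort$marks$CMP$H3K27me3$regions)
message(sprintf("H3K9me3 at polycomb regions: %.0f bp inside vs %.0f bp outside LOCKs (p = %.2g)",
                coq$mean_inside, coq$mean_outside, coq$test$p.value))

# methylation depression inside myeloid-retained domains
mt <- methylation_test(cohort$methyl$CMP, cohort$methyl$Monocyte,
                       retained[, .(chrom, start, end)])
message(sprintf("CpG methylation in retained domains: CMP - monocyte = %.3f (p = %.2g)",
                mt$delta_mean, mt$test$p.value))
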