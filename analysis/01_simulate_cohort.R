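#!/usr/bin/env Rscript
# Step 1: generate the synthetic 8-cell-type cord-blood cohort.
#
# Produces, for 4 progenitor (CD34+CD38-, CMP, GMP, MEP), 2 mature myeloid
# (monocyte, erythroblast) and 2 mature lymphoid (B, T) populations:
# enriched regions and binned tag tracks for six histone marks, a gene x
# cell-type expression table with GC bias and planted differential genes,
# CpG methylation tracks, a LAD annotation and a motif occurrence map — plus
# the ground-truth ledger the later steps are checked against. Writing the
# full cohort to disk is optional (set WRITE_DIR); all later steps rebuild
# it from the seed, which is cheaper than parsing it back.

suppressPackageStartupMessages({
  library(data.table)
  library(lockscape)
})

seed <- 7
dir.create("results", showWarnings = FALSE)

cohort <- simulate_cohort(cohort_spec(seed = seed))
print(cohort)

summary <- data.table(
  cell_type = cohort$cell_types$name,
  class = cohort$cell_types$class,
  k27me3_regions = vapply(cohort$marks, function(m) nrow(m$H3K27me3$regions), 1L),
  k27me3_bp = vapply(cohort$marks, function(m)
    total_bp(merge_intervals(m$H3K27me3$regions)), 1),
  k27ac_regions = vapply(cohort$marks, function(m) nrow(m$H3K27ac$regions), 1L),
  broad_gt_100kb = vapply(cohort$marks, function(m)
    large_region_count(merge_intervals(m$H3K27me3$regions, max_gap = 0), 1e5), 1L))
fwrite(summary, "results/01_cohort_summary.tsv", sep = "\t")
print(summary)

message("True LOCKs: ", nrow(cohort$truth$locks), " (",
        sum(cohort$truth$locks$retained_myeloid), " retained in myeloid)")
message("Planted DE genes per contrast: ",
        cohort$truth$de[, .N, by = sample]$N[1])

write_dir <- Sys.getenv("WRITE_DIR", "")
if (nzchar(write_dir)) {
  message("Writing cohort files to ", write_dir)
  write_cohort(cohort, write_dir)
}
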