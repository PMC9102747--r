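#' Call LOCKs (large organized chromatin K-modification domains)
#'
#' Broad repressive-mark peaks are clustered into domains: peaks shorter than
#' `MinLength` are dropped; remaining peaks on a chromosome are stitched when
#' the inter-peak gap is at most `G = exp(median + WScutoff * IQR)` of the
#' log inter-peak gaps of that chromosome; clusters with at least
#' `peakNumMin` peaks are kept; cluster spans below `min_lock_width` (100 Kb)
#' are eliminated. Chromosomes with fewer than 3 surviving peaks fall back to
#' the genome-wide gap threshold.
#'
#' @param peaks interval table of enriched regions (one cell type, one mark).
#' @param WScutoff dispersion multiplier on the log-gap IQR (default 1.5).
#' @param MinLength minimum peak width in bp (default 1000).
#' @param peakNumMin minimum peaks per cluster (default 2).
#' @param min_lock_width minimum LOCK span in bp (default 100,000).
#' @return data.table with chrom, start, end, lock_id, n_peaks, peak_bp
#'   (marked bp within the LOCK); disjoint within the input set.
#' @export
call_locks <- function(peaks, WScutoff = 1.5, MinLength = 1000,
                       peakNumMin = 2, min_lock_width = 100000) {
  peaks <- sort_intervals(as_intervals(peaks))
  peaks <- peaks[end - start >= MinLength]
  empty <- data.table(chrom = character(), start = numeric(), end = numeric(),
                      lock_id = character(), n_peaks = integer(), peak_bp = numeric())
  if (nrow(peaks) == 0L) {
    warning("no peaks pass MinLength; empty LOCK set", call. = FALSE)
    return(empty)
  }
  counts <- peaks[, .N, by = chrom]
  if (all(counts$N < 3)) {
    warning("fewer than 3 peaks on every chromosome; empty LOCK set", call. = FALSE)
    return(empty)
  }
  gaps_of <- function(s, e) pmax(s[-1] - e[-length(e)], 1)  # floor at 1 bp for logs
  all_gaps <- peaks[, if (.N >= 2) .(gap = gaps_of(start, end)), by = chrom]$gap
  lg_global <- stats::median(log(all_gaps)) + WScutoff * stats::IQR(log(all_gaps))
  out <- peaks[, {
    logG <- if (.N >= 3) {
      lg <- log(gaps_of(start, end))
      stats::median(lg) + WScutoff * stats::IQR(lg)
    } else {
      lg_global
    }
    gap <- if (.N >= 2) start[-1] - cummax(end)[-.N] else numeric(0)
    # compare in log space with a tolerance so a gap exactly at the
    # threshold stitches despite floating-point rounding
    brk <- log(pmax(gap, 1)) > logG + 1e-9
    cl <- cumsum(c(1L, as.integer(brk)))
    dt <- data.table(start = start, end = end, cl = cl)
    dt[, .(start = min(start), end = max(end), n_peaks = .N,
           peak_bp = total_bp(merge_intervals(data.table(chrom = "x", start = start, end = end)))),
       by = cl]
  }, by = chrom]
  out <- out[n_peaks >= peakNumMin & (end - start) >= min_lock_width]
  out[, cl := NULL]
  setorderv(out, c("chrom", "start", "end"))
  out[, lock_id := sprintf("lock_%04d", seq_len(.N))]
  out[, .(chrom, start, end, lock_id, n_peaks, peak_bp)]
}

#' Compare LOCK sets across cell types
#'
#' A reference LOCK counts as retained in a target cell type when some
#' target LOCK matches it with reciprocal overlap >= `min_reciprocal`
#' (default 25%); otherwise it is lost. Also reports, per target, the
#' fraction of target LOCKs that overlap the reference (the "remaining LOCKs
#' overlap progenitor LOCKs" statistic).
#'
#' @param reference LOCK table (from [call_locks()] or the bp-wise group
#'   intersection of several cell types).
#' @param others named list of LOCK tables.
#' @param min_reciprocal reciprocal-overlap identity threshold.
#' @return list with `summary` (per target: n_reference, n_target, retained,
#'   lost, retained_frac, target_in_reference_frac) and `retained` (logical
#'   matrix reference LOCKs x targets).
#' @export
compare_locks <- function(reference, others, min_reciprocal = 0.25) {
  reference <- as.data.table(reference)
  stopifnot(is.list(others), !is.null(names(others)))
  ret <- matrix(FALSE, nrow(reference), length(others),
                dimnames = list(reference$lock_id, names(others)))
  sm <- rbindlist(lapply(names(others), function(ct) {
    tgt <- as.data.table(others[[ct]])
    r <- if (nrow(tgt)) reciprocal_overlap(reference, tgt) >= min_reciprocal
         else rep(FALSE, nrow(reference))
    ret[, ct] <<- r
    t_in_ref <- if (nrow(tgt)) mean(reciprocal_overlap(tgt, reference) >= min_reciprocal)
                else NA_real_
    data.table(target = ct, n_reference = nrow(reference), n_target = nrow(tgt),
               retained = sum(r), lost = sum(!r), retained_frac = mean(r),
               target_in_reference_frac = t_in_ref)
  }))
  list(summary = sm, retained = ret)
}

#' Group intersection of LOCK sets
#'
#' The "LOCKs in all progenitors" construct: bp-wise intersection of the
#' merged per-cell-type LOCK sets, with the minimum-width filter re-applied.
#'
#' @param locksets list of LOCK tables.
#' @param min_lock_width minimum width after intersection (default 100 Kb).
#' @return interval table with lock_id.
#' @export
locks_intersection <- function(locksets, min_lock_width = 100000) {
  stopifnot(length(locksets) >= 1)
  acc <- merge_intervals(as.data.table(locksets[[1]]))
  for (k in seq_along(locksets)[-1]) {
    acc <- intersect_intervals(acc, as.data.table(locksets[[k]]))
    if (nrow(acc) == 0L) break
  }
  acc <- acc[end - start >= min_lock_width]
  if (nrow(acc)) acc[, lock_id := sprintf("lock_%04d", seq_len(.N))]
  else acc[, lock_id := character(0)]
  acc[]
}

#' Contraction statistics of marked segments within LOCKs
#'
#' For each cell type: total marked bp within each LOCK and the widths of
#' contiguous enriched segments inside the LOCKs (the quantity that contracts
#' from ~hundreds of Kb in progenitors to tens of Kb in mature myeloid
#' cells). Group contrasts use a Welch two-sided t-test on log segment
#' widths.
#'
#' @param locks LOCK interval table (the domains to profile within).
#' @param mark_regions_by_celltype named list of enriched-region tables.
#' @return list with `per_lock` (cell_type, lock_id, marked_bp), `segments`
#'   (cell_type, chrom, start, end, width) and `summary` (cell_type,
#'   mean_segment_width, total_marked_bp, n_segments).
#' @export
contraction_stats <- function(locks, mark_regions_by_celltype) {
  locks <- as.data.table(locks)
  per_lock <- list(); segs <- list()
  for (ct in names(mark_regions_by_celltype)) {
    mk <- merge_intervals(as.data.table(mark_regions_by_celltype[[ct]]))
    per_lock[[ct]] <- data.table(cell_type = ct, lock_id = locks$lock_id,
                                 marked_bp = overlap_bp(locks, mk))
    sg <- intersect_intervals(mk, locks)
    if (nrow(sg)) segs[[ct]] <- data.table(cell_type = ct, sg, width = sg$end - sg$start)
  }
  per_lock <- rbindlist(per_lock)
  segs <- rbindlist(segs)
  summary <- if (nrow(segs)) {
    segs[, .(mean_segment_width = mean(width), n_segments = .N,
             total_marked_bp = sum(width)), by = cell_type]
  } else data.table(cell_type = character(), mean_segment_width = numeric(),
                    n_segments = integer(), total_marked_bp = numeric())
  list(per_lock = per_lock, segments = segs, summary = summary)
}

#' Welch t-test on log segment widths between two groups
#' @param widths_a,widths_b numeric vectors of segment widths (bp).
#' @return htest object.
#' @export
segment_width_test <- function(widths_a, widths_b) {
  stats::t.test(log(widths_a), log(widths_b), var.equal = FALSE)
}

#' LOCK overlap with lamina-associated domains
#'
#' A LOCK counts as LAD-overlapping when it shares at least one bp with the
#' merged LAD set; the bp-level fraction of LOCK bases inside LADs is also
#' reported.
#'
#' @param locks LOCK interval table.
#' @param lads LAD interval table.
#' @return list with `lock_frac` (fraction of LOCKs overlapping), `bp_frac`
#'   (fraction of LOCK bp inside LADs) and the per-LOCK overlap bp.
#' @export
lad_overlap <- function(locks, lads) {
  locks <- as.data.table(locks)
  if (nrow(locks) == 0L) return(list(lock_frac = NA_real_, bp_frac = NA_real_,
                                     per_lock = numeric(0)))
  bp <- overlap_bp(locks, lads)
  list(lock_frac = mean(bp > 0), bp_frac = sum(bp) / total_bp(locks), per_lock = bp)
}

#' H3K9me3 co-occupancy of polycomb regions inside versus outside LOCKs
#'
#' Each H3K27me3-enriched region is assigned inside LOCKs when more than half
#' of its bases fall within the LOCK set; its H3K9me3 occupancy is the bp it
#' shares with the merged H3K9me3 set. The contrast is a Welch two-sided
#' t-test on log10(bp + 1) per region.
#'
#' @param locks LOCK interval table.
#' @param k9_regions H3K9me3 enriched regions.
#' @param k27_regions H3K27me3 enriched regions (the polycomb units).
#' @return list with `per_region` table (inside flag, k9_bp), group means and
#'   the `test` htest.
#' @export
co_occupancy <- function(locks, k9_regions, k27_regions) {
  k27 <- merge_intervals(as.data.table(k27_regions))
  inside <- coverage_fraction(k27, locks) > 0.5
  k9bp <- overlap_bp(k27, k9_regions)
  if (!any(inside) || all(inside)) {
    stop("polycomb regions fall entirely inside or outside LOCKs; no contrast")
  }
  tt <- tryCatch(
    stats::t.test(log10(k9bp[inside] + 1), log10(k9bp[!inside] + 1),
                  var.equal = FALSE),
    error = function(e) NULL)   # constant occupancy in a group: no test
  list(per_region = data.table(k27, inside = inside, k9_bp = k9bp),
       mean_inside = mean(k9bp[inside]), mean_outside = mean(k9bp[!inside]),
       test = tt)
}

#' Pool fractional CpG methylation within regions
#'
#' @param methyl data.table with chrom, pos, fraction (one cell type).
#' @param regions interval table; must be non-empty.
#' @return numeric vector of per-CpG fractional methylation inside regions.
#' @export
methylation_in_regions <- function(methyl, regions) {
  regions <- merge_intervals(as.data.table(regions))
  if (nrow(regions) == 0L) stop("empty region set")
  m <- as.data.table(methyl)
  cpg <- data.table(chrom = m$chrom, start = m$pos, end = m$pos + 1)
  m$fraction[overlaps_any(cpg, regions)]
}

#' Welch t-test on pooled CpG methylation between two cell types
#' @param methyl_a,methyl_b methylation tables (chrom, pos, fraction).
#' @param regions interval table over which CpGs are pooled.
#' @return list with delta_mean (a minus b), the two pooled vectors' sizes
#'   and the htest.
#' @export
methylation_test <- function(methyl_a, methyl_b, regions) {
  va <- methylation_in_regions(methyl_a, regions)
  vb <- methylation_in_regions(methyl_b, regions)
  if (length(va) < 2 || length(vb) < 2) stop("fewer than 2 CpGs in regions")
  tt <- stats::t.test(va, vb, var.equal = FALSE)
  list(delta_mean = mean(va) - mean(vb), n_a = length(va), n_b = length(vb),
       test = tt)
}
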