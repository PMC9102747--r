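#' Quantile normalization of a signal matrix
#'
#' Every column is mapped onto the common reference distribution given by the
#' row-wise mean of the sorted columns; ties within a column receive the
#' average of the reference values at their tied positions. Column rank
#' order is preserved.
#'
#' @param mat numeric matrix (regions x cell types).
#' @return normalized matrix, same dimnames.
#' @export
quantile_normalize <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 2) return(mat)
  if (nrow(mat) == 1) {
    out <- matrix(mean(mat), 1, ncol(mat), dimnames = dimnames(mat))
    return(out)
  }
  ref <- rowMeans(apply(mat, 2, sort))
  out <- apply(mat, 2, function(col) {
    r <- rank(col, ties.method = "average")
    stats::approx(seq_along(ref), ref, xout = r, rule = 2)$y
  })
  dimnames(out) <- dimnames(mat)
  out
}

#' Build the enhancer catalogue
#'
#' Union of all cell types' H3K27ac enriched regions; regions overlapping any
#' TSS +/- `tss_halfwidth` window are discarded; per-cell-type raw H3K27ac
#' tags are subsampled to the lowest library depth by binomial thinning with
#' a fixed seed; regions whose thinned tags do not exceed `tag_min` in any
#' cell type are dropped. Signal matrices (tag density per Kb) for H3K27ac
#' (post-thinning) and H3K4me1 are quantile normalized across regions within
#' each cell type.
#'
#' @param k27ac_peaks named list of per-cell-type enriched-region tables.
#' @param k27ac_tracks named list of per-cell-type [signal_track()]s (depths
#'   taken from the tracks).
#' @param genes gene annotation (protein-coding TSS define the exclusion
#'   windows).
#' @param k4me1_tracks optional named list of H3K4me1 tracks for primed-state
#'   signal.
#' @param tss_halfwidth TSS exclusion half-width (default 2000).
#' @param tag_min raw-tag floor; a region needs tags > tag_min in at least
#'   one cell type (default 40, strict).
#' @param seed seed for the binomial thinning (default 1).
#' @return object of class `enhancer_catalogue`: list with `regions`
#'   (region_id, chrom, start, end), `tags` (thinned H3K27ac tag matrix),
#'   `signal` (quantile-normalized H3K27ac density), `signal_k4me1`
#'   (quantile-normalized H3K4me1 density or NULL), `depths`, `min_depth`.
#' @export
build_catalogue <- function(k27ac_peaks, k27ac_tracks, genes,
                            k4me1_tracks = NULL, tss_halfwidth = 2000,
                            tag_min = 40, seed = 1) {
  stopifnot(length(k27ac_peaks) >= 2, all(names(k27ac_peaks) %in% names(k27ac_tracks)))
  cts <- names(k27ac_peaks)
  union <- merge_intervals(rbindlist(lapply(k27ac_peaks, as_intervals)))
  g <- as.data.table(genes)
  if ("biotype" %in% names(g)) g <- g[biotype == "protein_coding"]
  tssw <- promoter_windows(g, tss_halfwidth)
  union <- union[!overlaps_any(union, tssw)]
  if (nrow(union) == 0L) stop("empty enhancer union after TSS exclusion")
  depths <- vapply(k27ac_tracks[cts], function(t) t$depth, numeric(1))
  min_depth <- min(depths)
  raw <- vapply(cts, function(ct) region_tag_count(k27ac_tracks[[ct]], union),
                numeric(nrow(union)))
  raw <- matrix(raw, nrow = nrow(union), dimnames = list(NULL, cts))
  thinned <- with_seed(seed, {
    out <- raw
    for (ct in cts) {
      n <- round(raw[, ct])
      out[, ct] <- stats::rbinom(length(n), n, min_depth / depths[[ct]])
    }
    out
  })
  keep <- apply(thinned, 1, max) > tag_min
  if (!any(keep)) stop("no region passes the raw-tag floor")
  union <- union[keep]
  thinned <- thinned[keep, , drop = FALSE]
  union[, region_id := sprintf("enh_%05d", seq_len(.N))]
  width_kb <- (union$end - union$start) / 1000
  signal <- quantile_normalize(thinned / width_kb)
  signal_k4 <- NULL
  if (!is.null(k4me1_tracks)) {
    k4 <- vapply(cts, function(ct) region_tag_count(k4me1_tracks[[ct]], union),
                 numeric(nrow(union)))
    k4 <- matrix(k4, nrow = nrow(union), dimnames = list(NULL, cts))
    signal_k4 <- quantile_normalize(k4 / width_kb)
    rownames(signal_k4) <- union$region_id
  }
  rownames(thinned) <- rownames(signal) <- union$region_id
  structure(list(regions = union[, .(region_id, chrom, start, end)],
                 tags = thinned, signal = signal, signal_k4me1 = signal_k4,
                 depths = depths, min_depth = min_depth,
                 cell_types = cts, tag_min = tag_min),
            class = "enhancer_catalogue")
}

#' @export
print.enhancer_catalogue <- function(x, ...) {
  cat(sprintf("enhancer_catalogue: %d regions x %d cell types\n",
              nrow(x$regions), length(x$cell_types)))
  invisible(x)
}

#' Classify enhancer states per cell type
#'
#' Active: quantile-normalized H3K27ac signal strictly above `active_min`.
#' Primed: not active and H3K4me1 signal strictly above `primed_min`.
#' States are exclusive; "total enhancers" of a cell type means
#' active + primed.
#'
#' @param catalogue an [build_catalogue()] result.
#' @param active_min H3K27ac signal floor for active (default 25).
#' @param primed_min H3K4me1 signal floor for primed (default 40).
#' @return character matrix regions x cell types with values none/primed/
#'   active; attribute `counts` holds per-cell-type state counts.
#' @export
classify_states <- function(catalogue, active_min = 25, primed_min = 40) {
  active <- catalogue$signal > active_min
  primed <- if (!is.null(catalogue$signal_k4me1)) {
    !active & catalogue$signal_k4me1 > primed_min
  } else matrix(FALSE, nrow(active), ncol(active), dimnames = dimnames(active))
  states <- matrix("none", nrow(active), ncol(active), dimnames = dimnames(active))
  states[primed] <- "primed"
  states[active] <- "active"
  counts <- apply(states, 2, function(s) table(factor(s, c("none", "primed", "active"))))
  attr(states, "counts") <- counts
  states
}

#' Gains and losses of enhancers relative to a reference cell type
#'
#' Present means state != none; active means state == active. Gained:
#' present (active) in the target but not the reference; lost: the reverse.
#'
#' @param states matrix from [classify_states()].
#' @param reference_cell reference column name.
#' @return data.table per cell type with total/active gained and lost counts.
#' @export
trace_gain_loss <- function(states, reference_cell) {
  if (!reference_cell %in% colnames(states)) stop("reference cell type absent")
  ref_tot <- states[, reference_cell] != "none"
  ref_act <- states[, reference_cell] == "active"
  rbindlist(lapply(colnames(states), function(ct) {
    tot <- states[, ct] != "none"; act <- states[, ct] == "active"
    data.table(cell_type = ct,
               total_gained = sum(tot & !ref_tot), total_lost = sum(!tot & ref_tot),
               active_gained = sum(act & !ref_act), active_lost = sum(!act & ref_act))
  }))
}

#' Provenance of a mature cell type's enhancers
#'
#' Among regions present (or active, with `active_only`) in the mature cell
#' type: the percentage also present in the most primitive reference, the
#' percentage present in another progenitor but not the reference, and the
#' percentage unique to the mature cell type. Region identity is membership
#' in the shared catalogue union.
#'
#' @param states matrix from [classify_states()].
#' @param mature_cell target cell type.
#' @param reference_cell most primitive progenitor (CD34+CD38- analogue).
#' @param progenitor_cells other progenitor cell types.
#' @param active_only restrict to active enhancers (default FALSE: present).
#' @return list of percentages in_reference, in_progenitors, unique and n.
#' @export
provenance_fraction <- function(states, mature_cell, reference_cell,
                                progenitor_cells, active_only = FALSE) {
  pres <- function(ct) if (active_only) states[, ct] == "active" else states[, ct] != "none"
  tgt <- pres(mature_cell)
  if (!any(tgt)) return(list(in_reference = NA_real_, in_progenitors = NA_real_,
                             unique = NA_real_, n = 0L))
  in_ref <- pres(reference_cell)
  in_prog <- Reduce(`|`, lapply(progenitor_cells, pres))
  a <- mean(in_ref[tgt]) * 100
  b <- mean((!in_ref & in_prog)[tgt]) * 100
  list(in_reference = a, in_progenitors = b, unique = 100 - a - b, n = sum(tgt))
}

#' Call super-enhancers by the rank-curve tangent rule
#'
#' TSS-proximal peaks are removed, remaining enriched regions stitched within
#' `stitch_gap`, each stitched region scored by its total tag count, and
#' regions ranked by ascending signal. On the curve scaled to the unit
#' square, the cutoff is the tangent point where the slope equals 1
#' (the point furthest below the diagonal); super-enhancers are the regions
#' above the cutoff. The cutoff is scale invariant in the signal.
#'
#' @param peaks enriched-region table (one cell type).
#' @param track the cell type's [signal_track()].
#' @param genes gene annotation for TSS exclusion.
#' @param stitch_gap stitching distance bp (default 12,500).
#' @param tss_halfwidth TSS exclusion half-width (default 2000).
#' @return data.table of stitched regions with signal, rank, super flag;
#'   attributes `cutoff_signal` and `degenerate`.
#' @export
call_super_enhancers <- function(peaks, track, genes, stitch_gap = 12500,
                                 tss_halfwidth = 2000) {
  p <- as_intervals(peaks)
  g <- as.data.table(genes)
  if ("biotype" %in% names(g)) g <- g[biotype == "protein_coding"]
  tssw <- promoter_windows(g, tss_halfwidth)
  p <- p[!overlaps_any(p, tssw)]
  if (nrow(p) == 0L) stop("no peaks left after TSS exclusion")
  st <- merge_intervals(p, max_gap = stitch_gap)
  st[, signal := region_tag_count(track, st)]
  setorderv(st, "signal")
  st[, rank := seq_len(.N)]
  n <- nrow(st)
  if (n == 1L) {
    st[, super := TRUE]
    data.table::setattr(st, "cutoff_signal", st$signal[1])
    data.table::setattr(st, "degenerate", TRUE)
    return(st[])
  }
  x <- (st$rank - 1) / (n - 1)
  rng <- max(st$signal) - min(st$signal)
  y <- if (rng > 0) (st$signal - min(st$signal)) / rng else rep(0, n)
  d <- y - x
  tol <- 1e-9
  ties <- which(d <= min(d) + tol)
  cut_idx <- ties[ceiling(length(ties) / 2)]   # midpoint on flat (linear) curves
  degenerate <- rng == 0 || length(ties) > max(2L, 0.1 * n)
  st[, super := rank > cut_idx]
  setorderv(st, c("chrom", "start"))
  data.table::setattr(st, "cutoff_signal", st$signal[match(cut_idx, st$rank)])
  data.table::setattr(st, "degenerate", degenerate)
  st[]
}

#' Fraction of cell-type-specific active enhancers inside super-enhancers
#'
#' Specific means active in the target cell type and in none of the others;
#' a region is inside when it shares at least one bp with the cell type's
#' super regions.
#'
#' @param catalogue an [build_catalogue()] result.
#' @param states matrix from [classify_states()].
#' @param se super-enhancer table from [call_super_enhancers()] for the
#'   target cell type.
#' @param cell target cell type.
#' @param other_cells cell types defining specificity.
#' @return list with fraction, n_specific.
#' @export
specific_active_in_se <- function(catalogue, states, se, cell, other_cells) {
  spec <- states[, cell] == "active" &
    !Reduce(`|`, lapply(other_cells, function(ct) states[, ct] == "active"))
  if (!any(spec)) return(list(fraction = NA_real_, n_specific = 0L))
  super <- as.data.table(se)[super == TRUE]
  if (nrow(super) == 0L) return(list(fraction = 0, n_specific = sum(spec)))
  inside <- overlaps_any(catalogue$regions[spec], super)
  list(fraction = mean(inside), n_specific = sum(spec))
}

#' Associate catalogue regions with their nearest promoter
#'
#' Nearest protein-coding TSS per region (distance 0 when the TSS falls
#' inside the region); associations farther than `max_dist` are eliminated.
#' Distance ties break toward the lexicographically smaller gene id.
#'
#' @param catalogue an [build_catalogue()] result (or interval table with
#'   region_id).
#' @param genes gene annotation.
#' @param max_dist maximum region-promoter distance bp (default 50,000).
#' @return data.table region_id, gene_id, distance.
#' @export
associate_genes <- function(catalogue, genes, max_dist = 50000) {
  regions <- if (inherits(catalogue, "enhancer_catalogue")) catalogue$regions
             else as.data.table(catalogue)
  g <- as.data.table(genes)
  if ("biotype" %in% names(g)) g <- g[biotype == "protein_coding"]
  res <- rbindlist(lapply(unique(regions$chrom), function(ch) {
    r <- regions[chrom == ch]
    gg <- g[chrom == ch]
    if (nrow(gg) == 0L) return(NULL)
    gg <- gg[order(tss, gene_id)]
    rbindlist(lapply(seq_len(nrow(r)), function(k) {
      dist <- pmax(0, pmax(gg$tss - r$end[k] + 1, r$start[k] - gg$tss))
      m <- min(dist)
      cand <- gg$gene_id[dist == m]
      data.table(region_id = r$region_id[k], gene_id = sort(cand)[1], distance = m)
    }))
  }))
  res[distance <= max_dist]
}

#' Methylation at a class of enhancers
#'
#' Pools fractional CpG methylation over catalogue regions in the selected
#' state for each cell type, and contrasts two groups of cell types with a
#' Welch two-sided t-test.
#'
#' @param methyl_by_celltype named list of methylation tables.
#' @param catalogue an [build_catalogue()] result.
#' @param region_ids the enhancer regions to pool over (e.g. active in a
#'   mature cell type).
#' @param group_a,group_b character vectors of cell type names.
#' @return list with per-cell-type means, delta_mean (a minus b) and htest.
#' @export
methylation_at_enhancers <- function(methyl_by_celltype, catalogue, region_ids,
                                     group_a, group_b) {
  regions <- catalogue$regions[region_id %in% region_ids]
  if (nrow(regions) == 0L) stop("no regions selected")
  pool <- function(cts) unlist(lapply(cts, function(ct) {
    methylation_in_regions(methyl_by_celltype[[ct]], regions)
  }))
  va <- pool(group_a); vb <- pool(group_b)
  if (length(va) < 2 || length(vb) < 2) stop("fewer than 2 CpGs in selected enhancers")
  means <- vapply(names(methyl_by_celltype), function(ct) {
    mean(methylation_in_regions(methyl_by_celltype[[ct]], regions))
  }, numeric(1))
  list(means = means, delta_mean = mean(va) - mean(vb),
       test = stats::t.test(va, vb, var.equal = FALSE))
}

#' Paired expression contrast over enhancer-associated genes
#'
#' Wilcoxon signed-rank test comparing RPKM of the genes associated with a
#' set of enhancers between two cell types.
#'
#' @param table an [expression_table()].
#' @param gene_ids associated genes.
#' @param cell,reference sample names.
#' @return htest object.
#' @export
paired_expression_test <- function(table, gene_ids, cell, reference) {
  idx <- match(intersect(gene_ids, table$gene_id), table$gene_id)
  if (length(idx) < 2) stop("fewer than 2 associated genes with expression")
  suppressWarnings(stats::wilcox.test(table$rpkm[idx, cell],
                                      table$rpkm[idx, reference], paired = TRUE))
}
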