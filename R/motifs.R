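#' Read / write a motif occurrence map
#'
#' TSV with header columns motif_id, tf_gene_id, region_id: one row per
#' motif occurrence in a catalogue region (derived upstream from 300-bp
#' windows centered on the regions; PWM scanning is not re-done here).
#'
#' @param path file path.
#' @return data.table motif_id, tf_gene_id, region_id.
#' @export
read_motif_map <- function(path) {
  x <- fread(path, header = TRUE, sep = "\t")
  need <- c("motif_id", "tf_gene_id", "region_id")
  if (!all(need %in% names(x))) {
    stop("motif map requires columns: ", paste(need, collapse = ", "))
  }
  x[, need, with = FALSE]
}

#' @rdname read_motif_map
#' @param map motif map table.
#' @export
write_motif_map <- function(map, path) {
  fwrite(as.data.table(map), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Drop motifs whose transcription factor is not expressed
#'
#' Motifs for TFs with expression below 1 RPKM across all cell types are
#' eliminated; a TF at or above the threshold in at least one cell type is
#' kept (strict "< 1" elimination).
#'
#' @param map motif map (motif_id, tf_gene_id, region_id).
#' @param table an [expression_table()] covering the TF genes.
#' @param min_rpkm elimination threshold (default 1).
#' @return filtered motif map.
#' @export
filter_expressed_tfs <- function(map, table, min_rpkm = 1) {
  map <- as.data.table(map)
  if (nrow(map) == 0L) return(map)
  max_rpkm <- apply(table$rpkm, 1, max)
  tf_max <- max_rpkm[map$tf_gene_id]
  tf_max[is.na(tf_max)] <- 0
  map[tf_max >= min_rpkm]
}

#' Motif enrichment scores relative to a reference cell type
#'
#' For each motif, the cumulative quantile-normalized H3K27ac signal over its
#' regions is computed for every cell type; the standard score (z across
#' cell types) of the cell of interest minus that of the reference is the
#' enrichment score. A motif/cell-type pair is flagged significant when the
#' region-level signals differ from the reference by a two-sided Wilcoxon
#' rank-sum test at BH q < `q_threshold`.
#'
#' @param map motif map (motif_id, tf_gene_id, region_id); duplicate region
#'   ids per motif are collapsed (sets, not multisets). Motifs with no valid
#'   catalogue region are dropped with a warning.
#' @param catalogue an [build_catalogue()] result.
#' @param reference_cell reference cell type (CD34+CD38- analogue).
#' @param q_threshold BH significance threshold (default 0.05).
#' @return data.table motif_id x cell_type with cumulative signal, z,
#'   enrichment (z - z_reference), p, q, significant.
#' @export
motif_scores <- function(map, catalogue, reference_cell, q_threshold = 0.05) {
  map <- unique(as.data.table(map)[, .(motif_id, tf_gene_id, region_id)])
  cts <- catalogue$cell_types
  if (!reference_cell %in% cts) stop("reference cell type absent: ", reference_cell)
  if (length(cts) < 2) stop("standard score undefined with a single cell type")
  known <- map$region_id %in% catalogue$regions$region_id
  if (any(!known)) {
    warning(sum(!known), " motif occurrences in unknown regions dropped", call. = FALSE)
    map <- map[known]
  }
  empty <- setdiff(unique(map$motif_id), map$motif_id)
  motifs <- unique(map$motif_id)
  if (!length(motifs)) {
    warning("no motif maps to a catalogue region", call. = FALSE)
    return(data.table(motif_id = character(), cell_type = character(),
                      cumulative = numeric(), z = numeric(), enrichment = numeric(),
                      p = numeric(), q = numeric(), significant = logical()))
  }
  sig <- catalogue$signal
  res <- rbindlist(lapply(motifs, function(m) {
    rid <- map[motif_id == m, region_id]
    rows <- match(rid, catalogue$regions$region_id)
    cum <- colSums(sig[rows, , drop = FALSE])
    z <- if (stats::sd(cum) > 0) (cum - mean(cum)) / stats::sd(cum) else cum * 0
    p <- vapply(cts, function(ct) {
      if (ct == reference_cell || length(rows) < 2) return(NA_real_)
      suppressWarnings(stats::wilcox.test(sig[rows, ct], sig[rows, reference_cell],
                                          paired = FALSE)$p.value)
    }, numeric(1))
    data.table(motif_id = m, cell_type = cts, cumulative = cum, z = z,
               enrichment = z - z[[reference_cell]], p = p)
  }))
  res[, q := NA_real_]
  nn <- !is.na(res$p)
  res$q[nn] <- stats::p.adjust(res$p[nn], method = "BH")
  res[, significant := !is.na(q) & q < q_threshold]
  res[]
}
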