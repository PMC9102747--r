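#' Promoter windows around annotated TSS
#'
#' Strand-oriented TSS +/- `halfwidth` windows, clipped to chromosome bounds
#' when sizes are supplied.
#'
#' @param genes gene annotation table (see [read_gene_annotation()]).
#' @param halfwidth window half-width in bp (default 2000).
#' @param chrom_sizes optional named sizes used for clipping.
#' @return interval table with gene_id as id and strand kept.
#' @export
promoter_windows <- function(genes, halfwidth = 2000, chrom_sizes = NULL) {
  g <- as.data.table(genes)
  w <- data.table(chrom = g$chrom, start = pmax(g$tss - halfwidth, 0),
                  end = g$tss + halfwidth, id = g$gene_id, strand = g$strand)
  if (!is.null(chrom_sizes)) {
    w[, end := pmin(end, chrom_sizes[chrom])]
  }
  w[end > start]
}

#' Promoter density matrix (genes x cell types)
#'
#' Normalized mark density (tags per Kb per 10M enriched tags) within TSS
#' +/- 2 Kb of protein-coding genes, for each cell type.
#'
#' @param tracks_by_celltype named list of [signal_track()]s.
#' @param genes gene annotation table; restricted to
#'   `biotype == "protein_coding"` when the column is present.
#' @param enriched_totals named numeric: per-cell-type total tags within that
#'   cell type's enriched regions (the normalization denominator).
#' @param halfwidth promoter half-width (default 2000).
#' @return numeric matrix, rownames gene ids, colnames cell types.
#' @export
promoter_density_matrix <- function(tracks_by_celltype, genes, enriched_totals,
                                    halfwidth = 2000) {
  g <- as.data.table(genes)
  if ("biotype" %in% names(g)) g <- g[biotype == "protein_coding"]
  sizes <- tracks_by_celltype[[1]]$chrom_sizes
  w <- promoter_windows(g, halfwidth, chrom_sizes = sizes)
  out <- matrix(0, nrow(w), length(tracks_by_celltype),
                dimnames = list(w$id, names(tracks_by_celltype)))
  for (ct in names(tracks_by_celltype)) {
    out[, ct] <- normalized_density(tracks_by_celltype[[ct]], w,
                                    within_enriched_total = enriched_totals[[ct]])
  }
  out
}

#' Aggregate positional promoter profile for one cell type
#'
#' Average normalized density in offset bins across all promoter windows,
#' oriented by strand (negative offsets are upstream of the TSS).
#'
#' @param track a [signal_track()].
#' @param genes gene annotation table.
#' @param enriched_total normalization denominator for this cell type.
#' @param halfwidth window half-width (default 2000).
#' @param bin offset bin width in bp (default 100).
#' @return data.table with offset (bin center relative to TSS) and density.
#' @export
promoter_profile <- function(track, genes, enriched_total, halfwidth = 2000,
                             bin = 100) {
  g <- as.data.table(genes)
  if ("biotype" %in% names(g)) g <- g[biotype == "protein_coding"]
  offs <- seq(-halfwidth, halfwidth - bin, by = bin)
  dens <- vapply(offs, function(o) {
    # strand-oriented: offset o on "-" genes maps to the mirrored window
    s <- ifelse(g$strand == "+", g$tss + o, g$tss - o - bin)
    w <- data.table(chrom = g$chrom, start = pmax(s, 0), end = pmax(s, 0) + bin)
    ok <- w$end <= track$chrom_sizes[w$chrom] & w$start >= 0
    mean(normalized_density(track, w[ok], enriched_total))
  }, numeric(1))
  data.table(offset = offs + bin / 2, density = dens)
}

#' Maximum-value normalization of a profile
#'
#' Scales a non-negative vector so its maximum is 1; an all-zero vector is
#' returned unchanged. With ties, the leftmost maximum attains 1 first.
#' @param x numeric vector or matrix (rows normalized).
#' @return same shape, max-normalized.
#' @export
max_normalize <- function(x) {
  if (is.matrix(x)) return(t(apply(x, 1, max_normalize)))
  m <- max(x)
  if (m > 0) x / m else x
}

#' Pairwise Spearman correlation and average-linkage clustering
#'
#' Rows with zero density in every column are removed to avoid tied-zero
#' inflation; clustering uses average linkage on 1 - R.
#'
#' @param mat numeric matrix (features x cell types).
#' @return list with `R` (Spearman matrix), `hclust` and `order`.
#' @export
correlation_cluster <- function(mat) {
  keep <- rowSums(mat != 0) >= 1
  mat <- mat[keep, , drop = FALSE]
  R <- stats::cor(mat, method = "spearman")
  hc <- stats::hclust(stats::as.dist(1 - R), method = "average")
  list(R = R, hclust = hc, order = colnames(mat)[hc$order])
}

#' Two-sample Kolmogorov-Smirnov test on promoter fragment positions
#'
#' Compares the positional distributions of immunoprecipitated fragments in
#' the promoter window between two cell types.
#'
#' @param positions_a,positions_b numeric vectors of fragment positions
#'   (offsets in the window).
#' @return list with D statistic and p value.
#' @export
ks_fragment_test <- function(positions_a, positions_b) {
  kt <- suppressWarnings(stats::ks.test(positions_a, positions_b))
  list(D = unname(kt$statistic), p = kt$p.value, test = kt)
}

#' Gene-body H3K27me3 mark states and retention/loss flows
#'
#' A gene is marked when more than `threshold` (20%) of its body is covered
#' by H3K27me3 enriched regions. For every non-reference cell type, genes
#' marked in the reference are classified as retained or lost (the Sankey
#' flow of the gene-level contraction analysis).
#'
#' @param k27_by_celltype named list of H3K27me3 enriched-region tables.
#' @param genes gene annotation table.
#' @param reference_cell name of the reference cell type.
#' @param threshold marked cutoff on covered fraction (strict >, default 0.20).
#' @return list with `states` (gene x cell type: fraction, marked), `flows`
#'   (cell_type, retained, lost) and `lost_genes` (named list).
#' @export
gene_mark_states <- function(k27_by_celltype, genes, reference_cell,
                             threshold = 0.20) {
  if (!reference_cell %in% names(k27_by_celltype)) {
    stop("reference cell type absent: ", reference_cell)
  }
  g <- as.data.table(genes)
  body <- data.table(chrom = g$chrom, start = g$start, end = g$end, id = g$gene_id)
  states <- rbindlist(lapply(names(k27_by_celltype), function(ct) {
    fr <- coverage_fraction(body, as.data.table(k27_by_celltype[[ct]]))
    data.table(gene_id = g$gene_id, cell_type = ct, fraction = fr,
               marked = fr > threshold)
  }))
  ref_marked <- states[cell_type == reference_cell & marked == TRUE, gene_id]
  flows <- states[cell_type != reference_cell & gene_id %in% ref_marked,
                  .(retained = sum(marked), lost = sum(!marked)), by = cell_type]
  lost_genes <- lapply(setdiff(names(k27_by_celltype), reference_cell), function(ct) {
    states[cell_type == ct & gene_id %in% ref_marked & marked == FALSE, gene_id]
  })
  names(lost_genes) <- setdiff(names(k27_by_celltype), reference_cell)
  list(states = states, flows = flows, lost_genes = lost_genes,
       reference_marked = ref_marked)
}

#' Overlap of H3K27me3-losing genes with upregulated genes
#'
#' Percentage of upregulated genes (in the target cell type versus the
#' reference) that also lost gene-body H3K27me3, with the absolute count.
#' An empty upregulated set reports 0% with n = 0.
#'
#' @param lost_genes character vector of genes losing the mark in the target.
#' @param de_result [define_de()] output for target vs reference, where
#'   call "up" means higher in the target sample.
#' @return list with percent, count, n_upregulated.
#' @export
loss_upregulation_overlap <- function(lost_genes, de_result) {
  up <- de_result[call == "up", gene_id]
  if (!length(up)) return(list(percent = 0, count = 0L, n_upregulated = 0L))
  count <- length(intersect(lost_genes, up))
  list(percent = 100 * count / length(up), count = count,
       n_upregulated = length(up))
}
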