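#' Simulate a GC-biased RNA-seq count table with planted DE genes
#'
#' Counts are negative binomial; each sample's mean is multiplied by a
#' sample-specific monotone multiplicative GC-bias curve
#' `exp(amp_s * (gc - 0.5))`, so fold-changes between samples acquire a
#' smooth trend in gene GC content that the GC renormalization must remove.
#' Planted differentially expressed genes shift the target sample's mean by
#' `2^lfc` relative to the reference (the first sample). RPKM is computed
#' from the realized counts, gene length and realized library depth, so a
#' zero-count gene has RPKM 0.
#'
#' @param n_genes number of genes (default 8000).
#' @param sample_names sample (cell type) names; first is the reference.
#' @param n_de number of DE genes to plant per non-reference sample when no
#'   explicit `de_table` is given (default 0).
#' @param de_lfc absolute log2 effect of auto-planted DE genes (default 2,
#'   i.e. 4-fold); signs alternate up/down.
#' @param de_min_base auto-planted DE genes are drawn from genes with
#'   baseline mean count at least this (default 150) - an effect planted on a
#'   gene with a handful of reads is not an effect.
#' @param de_table optional explicit plan: data.table(sample, gene, lfc)
#'   with gene as index into the gene vector.
#' @param gc_bias_amplitude half-spread of the per-sample GC log-bias slopes
#'   (default 1); 0 disables GC bias.
#' @param dispersion negative binomial size parameter (default 100).
#' @param base_meanlog,base_sdlog log-normal baseline mean counts
#'   (default log(120), 1.2).
#' @param genes optional gene annotation table supplying gene_id,
#'   gc_fraction and length (end - start); otherwise drawn.
#' @param silent_genes gene ids forced to near-zero expression (used to
#'   plant sub-1-RPKM transcription factors).
#' @param seed RNG seed.
#' @return list with `table` (an [expression_table()]) and `truth`
#'   (data.table sample, gene_id, lfc).
#' @export
simulate_counts <- function(n_genes = 8000, sample_names = c("A", "B"),
                            n_de = 0, de_lfc = 2, de_min_base = 150,
                            de_table = NULL, gc_bias_amplitude = 1,
                            dispersion = 100, base_meanlog = log(120),
                            base_sdlog = 1.2, genes = NULL,
                            silent_genes = character(0), seed = 1) {
  if (dispersion <= 0) stop("dispersion must be positive")
  with_seed(seed, {
    if (is.null(genes)) {
      gene_id <- sprintf("gene_%05d", seq_len(n_genes))
      gc <- 0.3 + 0.45 * stats::rbeta(n_genes, 6, 6)
      len <- pmin(pmax(round(exp(stats::rnorm(n_genes, log(3000), 0.6))), 500), 30000)
    } else {
      genes <- as.data.table(genes)
      gene_id <- genes$gene_id
      n_genes <- length(gene_id)
      gc <- genes$gc_fraction
      len <- genes$end - genes$start
    }
    base <- exp(stats::rnorm(n_genes, base_meanlog, base_sdlog))
    base[gene_id %in% silent_genes] <- 0.05
    ns <- length(sample_names)
    # evenly spread monotone GC log-bias slopes across samples
    amp <- if (ns == 1) 0 else seq(-gc_bias_amplitude, gc_bias_amplitude,
                                   length.out = ns)
    depth_factor <- stats::runif(ns, 0.85, 1.15)
    if (is.null(de_table)) {
      de_table <- data.table(sample = character(), gene = integer(), lfc = numeric())
      if (n_de > 0) {
        eligible <- which(base >= de_min_base & !(gene_id %in% silent_genes))
        if (length(eligible) < n_de) stop("too few expressed genes to plant DE")
        for (s in sample_names[-1]) {
          g <- sample(eligible, n_de)
          de_table <- rbind(de_table,
                           data.table(sample = s, gene = g,
                                      lfc = de_lfc * rep_len(c(1, -1), n_de)))
        }
      }
    }
    counts <- matrix(0L, n_genes, ns, dimnames = list(gene_id, sample_names))
    for (j in seq_len(ns)) {
      mu <- base * depth_factor[j] * exp(amp[j] * (gc - 0.5))
      de_j <- de_table[sample == sample_names[j]]
      if (nrow(de_j)) mu[de_j$gene] <- mu[de_j$gene] * 2^de_j$lfc
      counts[, j] <- stats::rnbinom(n_genes, size = dispersion, mu = mu)
    }
    depth <- colSums(counts)
    rpkm <- sweep(counts / (len / 1000), 2, depth / 1e6, "/")
    truth <- de_table[, .(sample, gene_id = gene_id[gene], lfc)]
    list(table = expression_table(gene_id, counts, rpkm, gc, len),
         truth = truth)
  })
}
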