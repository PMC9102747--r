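#' Gene-by-sample expression table
#'
#' Holds raw counts, RPKM, per-gene GC fraction and gene length with a shared
#' gene ordering; the input contract of the pairwise differential-expression
#' routine.
#'
#' @param gene_id character vector.
#' @param counts integer matrix genes x samples (>= 0).
#' @param rpkm numeric matrix, same shape, finite and >= 0.
#' @param gc_fraction per-gene GC fraction in \[0, 1\].
#' @param length_bp per-gene length in bp.
#' @return an object of class `expression_table`.
#' @export
expression_table <- function(gene_id, counts, rpkm, gc_fraction, length_bp) {
  counts <- as.matrix(counts); rpkm <- as.matrix(rpkm)
  stopifnot(length(gene_id) == nrow(counts), all(dim(counts) == dim(rpkm)),
            length(gc_fraction) == length(gene_id),
            length(length_bp) == length(gene_id))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(!is.finite(rpkm)) || any(rpkm < 0)) stop("RPKM must be finite and non-negative")
  if (any(gc_fraction < 0 | gc_fraction > 1)) stop("gc_fraction must be in [0,1]")
  rownames(counts) <- rownames(rpkm) <- gene_id
  structure(list(gene_id = gene_id, counts = counts, rpkm = rpkm,
                 gc_fraction = as.numeric(gc_fraction),
                 length_bp = as.numeric(length_bp)),
            class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d samples (%s)\n",
              length(x$gene_id), ncol(x$counts),
              paste(colnames(x$counts), collapse = ", ")))
  invisible(x)
}

#' Write / read an expression table as TSV
#'
#' Wide TSV with gene_id, gc_fraction, length_bp, then `count.<sample>` and
#' `rpkm.<sample>` columns.
#' @param x an [expression_table()].
#' @param path file path.
#' @export
write_expression_table <- function(x, path) {
  out <- data.table(gene_id = x$gene_id, gc_fraction = x$gc_fraction,
                    length_bp = x$length_bp)
  for (s in colnames(x$counts)) out[[paste0("count.", s)]] <- x$counts[, s]
  for (s in colnames(x$rpkm)) out[[paste0("rpkm.", s)]] <- x$rpkm[, s]
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' @rdname write_expression_table
#' @export
read_expression_table <- function(path) {
  x <- fread(path, header = TRUE, sep = "\t")
  cn <- grep("^count\\.", names(x), value = TRUE)
  rn <- grep("^rpkm\\.", names(x), value = TRUE)
  expression_table(x$gene_id,
                   as.matrix(x[, cn, with = FALSE]) |>
                     `colnames<-`(sub("^count\\.", "", cn)),
                   as.matrix(x[, rn, with = FALSE]) |>
                     `colnames<-`(sub("^rpkm\\.", "", rn)),
                   x$gc_fraction, x$length_bp)
}

#' Mode of a distribution by kernel density
#'
#' Gaussian-kernel density with Silverman's bandwidth, mode taken as the
#' argmax on a 512-point grid.
#' @param x numeric vector (length >= 2, non-constant).
#' @return numeric mode estimate.
#' @export
estimate_mode <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2 || stats::sd(x) == 0) {
    return(if (length(x)) x[1] else NA_real_)
  }
  d <- stats::density(x, bw = "nrd0", n = 512)
  d$x[which.max(d$y)]
}

# Internal: RPKM pseudocount equivalent to 0.5 raw reads for each gene/sample,
# used when forming log fold-changes so zero-count genes stay finite.
rpkm_pseudo <- function(table, sample) {
  depth <- sum(table$counts[, sample])
  0.5 / (table$length_bp / 1000) / (depth / 1e6)
}

# Internal: assign GC bins (quantile-based, n_bins over the GC values of the
# genes considered), then merge bins holding fewer than min_genes genes into
# their left neighbour (with a warning).
gc_bin_assign <- function(gc, n_bins, min_genes) {
  br <- unique(stats::quantile(gc, probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) return(rep(1L, length(gc)))   # constant GC: one bin
  bin <- cut(gc, breaks = br, include.lowest = TRUE, labels = FALSE)
  repeat {
    tab <- tabulate(bin, nbins = max(bin))
    small <- which(tab > 0 & tab < min_genes)
    if (!length(small) || max(bin) == 1) break
    b <- small[1]
    warning(sprintf("GC bin %d has %d genes (< %d); merging with neighbour",
                    b, tab[b], min_genes), call. = FALSE)
    nb <- if (b > 1) b - 1 else 2
    bin[bin == b] <- nb
    # compact labels
    bin <- match(bin, sort(unique(bin)))
  }
  bin
}

#' GC renormalization of a sample pair
#'
#' Fold-changes between two libraries show a systematic trend in gene GC
#' content. Under the assumption that the mode of the fold-change
#' distribution is GC independent, expression of sample_b is rescaled
#' multiplicatively within each of `n_gc_bins` GC bins so that the per-bin
#' mode of log2(RPKM_a / RPKM_b) lands on the global target mode (0 here:
#' most genes unchanged).
#'
#' @param table an [expression_table()].
#' @param sample_a,sample_b column names of the pair.
#' @param n_gc_bins number of GC bins (default 10).
#' @param min_genes minimum genes per GC bin before merging (default 50).
#' @param min_rpkm genes below this RPKM in both samples are excluded from
#'   bin fitting and flagged (default 0.1).
#' @return list with `rpkm_a`, `rpkm_b` (corrected), per-gene `gc_bin`,
#'   per-bin `correction` (multiplier applied to sample_b), logical `used`
#'   marking genes that passed the expression filter.
#' @export
gc_renormalize <- function(table, sample_a, sample_b, n_gc_bins = 10,
                           min_genes = 50, min_rpkm = 0.1) {
  a <- table$rpkm[, sample_a]; b <- table$rpkm[, sample_b]
  pa <- rpkm_pseudo(table, sample_a); pb <- rpkm_pseudo(table, sample_b)
  used <- a >= min_rpkm | b >= min_rpkm
  if (sum(used) < 2 * min_genes) stop("too few expressed genes for GC binning")
  bin <- rep(NA_integer_, length(a))
  bin[used] <- gc_bin_assign(table$gc_fraction[used], n_gc_bins, min_genes)
  lfc <- log2((a + pa) / (b + pb))
  nb <- max(bin, na.rm = TRUE)
  corr <- numeric(nb)
  for (k in seq_len(nb)) {
    corr[k] <- 2^estimate_mode(lfc[which(bin == k)])   # shift mode to 0
  }
  b_corr <- b
  idx <- which(used)
  b_corr[idx] <- b[idx] * corr[bin[idx]]
  list(rpkm_a = a, rpkm_b = b_corr, gc_bin = bin, correction = corr,
       used = used, pseudo_a = pa, pseudo_b = pb)
}

#' Quantile-wise Gaussian fit of log fold-changes
#'
#' Genes are binned into quantiles of their mean expression across the two
#' samples; within each bin a Gaussian is fitted to the log fold-change
#' distribution after removing extreme outliers (beyond median +/- 3 MAD).
#'
#' @param log_fc per-gene log2 fold-change.
#' @param mean_expr per-gene mean expression used for binning.
#' @param n_quantiles number of quantile bins (default 10).
#' @param trim_mads outlier trim rule in MAD units (default 3).
#' @param min_genes minimum genes per quantile bin (default 30).
#' @return list with per-bin data.table `fit` (bin, mu, sigma, n) and
#'   per-gene `bin` index.
#' @export
quantile_gaussian_fit <- function(log_fc, mean_expr, n_quantiles = 10,
                                  trim_mads = 3, min_genes = 30) {
  stopifnot(length(log_fc) == length(mean_expr))
  ok <- is.finite(log_fc) & is.finite(mean_expr)
  n_quantiles <- max(1L, min(n_quantiles, floor(sum(ok) / min_genes)))
  br <- unique(stats::quantile(mean_expr[ok], probs = seq(0, 1, length.out = n_quantiles + 1)))
  bin <- rep(NA_integer_, length(log_fc))
  bin[ok] <- cut(mean_expr[ok], breaks = br, include.lowest = TRUE, labels = FALSE)
  fit <- rbindlist(lapply(seq_len(max(bin, na.rm = TRUE)), function(k) {
    x <- log_fc[which(bin == k)]
    med <- stats::median(x); madx <- stats::mad(x)
    keep <- if (madx > 0) abs(x - med) <= trim_mads * madx else rep(TRUE, length(x))
    mu <- mean(x[keep]); sigma <- stats::sd(x[keep])
    if (!is.finite(sigma) || sigma == 0) {
      stop(sprintf("zero-variance log fold-change in expression quantile bin %d", k))
    }
    data.table(bin = k, mu = mu, sigma = sigma, n = sum(keep))
  }))
  list(fit = fit, bin = bin)
}

#' Pairwise differential expression (DEfine)
#'
#' The pairwise heuristic assumes that most genes (~90%) are not
#' differentially expressed between the two libraries. After GC
#' renormalization, each gene's log2 fold-change is standardized against the
#' Gaussian null fitted in its mean-expression quantile bin; two-sided
#' Gaussian p-values are corrected by Benjamini-Hochberg and calls made at
#' `q <= fdr`.
#'
#' @param table an [expression_table()].
#' @param sample_a,sample_b column names; fold-change is a over b.
#' @param fdr FDR threshold for calls (default 0.001, the study setting).
#' @param n_gc_bins,n_quantiles,min_rpkm,trim_mads tuning knobs, see
#'   [gc_renormalize()] and [quantile_gaussian_fit()].
#' @return data.table with gene_id, log2_fc, mean_expr, quantile_bin, z, p,
#'   q, call in \{up, down, ns\}; attribute `fit` holds the per-bin Gaussian
#'   parameters.
#' @export
define_de <- function(table, sample_a, sample_b, fdr = 0.001, n_gc_bins = 10,
                      n_quantiles = 10, min_rpkm = 0.1, trim_mads = 3) {
  gcn <- gc_renormalize(table, sample_a, sample_b, n_gc_bins = n_gc_bins,
                        min_rpkm = min_rpkm)
  a <- gcn$rpkm_a + gcn$pseudo_a
  b <- gcn$rpkm_b + gcn$pseudo_b
  lfc <- log2(a / b)
  mean_expr <- (gcn$rpkm_a + gcn$rpkm_b) / 2
  res <- data.table(gene_id = table$gene_id, log2_fc = lfc, mean_expr = mean_expr,
                    quantile_bin = NA_integer_, z = NA_real_, p = NA_real_,
                    q = NA_real_, call = "ns")
  idx <- which(gcn$used)
  qf <- quantile_gaussian_fit(lfc[idx], mean_expr[idx], n_quantiles = n_quantiles,
                              trim_mads = trim_mads)
  res$quantile_bin[idx] <- qf$bin
  res$z[idx] <- (lfc[idx] - qf$fit$mu[qf$bin]) / qf$fit$sigma[qf$bin]
  res$p[idx] <- 2 * stats::pnorm(-abs(res$z[idx]))
  res$q[idx] <- stats::p.adjust(res$p[idx], method = "BH")
  called <- !is.na(res$q) & res$q <= fdr
  res$call[called] <- ifelse(res$log2_fc[called] > 0, "up", "down")
  if (mean(called) > 0.5) {
    warning("more than 50% of genes called differential: the ~90% null ",
            "assumption of the pairwise heuristic is violated", call. = FALSE)
  }
  data.table::setattr(res, "fit", qf$fit)
  data.table::setattr(res, "gc_correction", gcn$correction)
  res[]
}
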