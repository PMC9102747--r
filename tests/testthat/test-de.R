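# helper: expression table straight from vectors of RPKM (counts chosen so
# pseudocounts are negligible)
mk_table <- function(rpkm_a, rpkm_b, gc, len = 1000) {
  n <- length(rpkm_a)
  expression_table(sprintf("g%05d", seq_len(n)),
                   counts = cbind(A = round(rpkm_a * 1000), B = round(rpkm_b * 1000)),
                   rpkm = cbind(A = rpkm_a, B = rpkm_b),
                   gc_fraction = gc, length_bp = rep_len(len, n))
}

test_that("gc_renormalize leaves identical samples untouched", {
  withr::local_seed(10)
  rpkm <- exp(stats::rnorm(2000, 2, 1))
  gc <- stats::runif(2000, 0.3, 0.7)
  gcn <- gc_renormalize(mk_table(rpkm, rpkm, gc), "A", "B")
  expect_true(all(abs(gcn$correction - 1) < 0.02))
  expect_equal(max(gcn$gc_bin, na.rm = TRUE), 10)
})

test_that("gc_renormalize recovers a planted monotone GC bias", {
  withr::local_seed(11)
  n <- 8000
  gc <- stats::runif(n, 0.3, 0.7)
  a <- exp(stats::rnorm(n, 2, 1))
  bias <- exp(0.9 * (gc - 0.5))
  b <- a * bias * exp(stats::rnorm(n, 0, 0.1))
  gcn <- gc_renormalize(mk_table(a, b, gc), "A", "B")
  # correction on sample_b should be ~1/bias at each bin center
  centers <- vapply(seq_len(max(gcn$gc_bin, na.rm = TRUE)), function(k) {
    stats::median(gc[which(gcn$gc_bin == k)])
  }, numeric(1))
  expect_true(all(abs(gcn$correction * exp(0.9 * (centers - 0.5)) - 1) < 0.05))
  # and the per-bin mode of the corrected fold-change is ~0
  lfc <- log2((gcn$rpkm_a + gcn$pseudo_a) / (gcn$rpkm_b + gcn$pseudo_b))
  modes <- vapply(seq_len(max(gcn$gc_bin, na.rm = TRUE)), function(k) {
    estimate_mode(lfc[which(gcn$gc_bin == k)])
  }, numeric(1))
  expect_true(all(abs(modes) < 0.05))
})

test_that("degenerate GC binning collapses to a single global shift", {
  withr::local_seed(12)
  rpkm <- exp(stats::rnorm(500, 2, 1))
  gc <- rep(0.5, 500)   # all genes in one bin
  gcn <- gc_renormalize(mk_table(rpkm, rpkm * 2, gc), "A", "B")
  expect_equal(length(gcn$correction), 1)
  # b is 2x a: the multiplicative correction halves sample b
  expect_equal(gcn$correction[1], 0.5, tolerance = 0.03)
  expect_equal(estimate_mode(log2(gcn$rpkm_a / gcn$rpkm_b)), 0, tolerance = 0.05)
})

test_that("sparse GC bins are merged with a warning", {
  withr::local_seed(16)
  n <- 1000
  gc <- c(rep(0.4, 480), rep(0.6, 480), rep(0.8, 40))
  rpkm <- exp(stats::rnorm(n, 2, 1))
  expect_warning(gcn <- gc_renormalize(mk_table(rpkm, rpkm, gc), "A", "B"),
                 "merging")
  tab <- table(gcn$gc_bin)
  expect_true(all(tab >= 50))
})

test_that("quantile_gaussian_fit recovers standard-normal parameters", {
  withr::local_seed(13)
  n <- 5000
  lfc <- stats::rnorm(n)
  me <- exp(stats::rnorm(n, 2, 1))
  qf <- quantile_gaussian_fit(lfc, me, n_quantiles = 5)
  expect_true(all(abs(qf$fit$mu) < 0.05))
  expect_true(all(abs(qf$fit$sigma - 1) < 0.07))
  expect_error(quantile_gaussian_fit(rep(1, 100), me[1:100]), "zero-variance")
})

test_that("the 3-MAD trim protects sigma from extreme outliers", {
  withr::local_seed(14)
  n <- 4000
  lfc <- stats::rnorm(n)
  out_idx <- sample(n, round(0.05 * n))
  lfc_out <- lfc
  lfc_out[out_idx] <- sample(c(-8, 8), length(out_idx), replace = TRUE)
  me <- exp(stats::rnorm(n, 2, 1))
  s_clean <- quantile_gaussian_fit(lfc, me, n_quantiles = 4)$fit$sigma
  s_out <- quantile_gaussian_fit(lfc_out, me, n_quantiles = 4)$fit$sigma
  expect_true(all(s_out / s_clean < 1.1))
})

test_that("a sample compared against itself yields zero calls", {
  withr::local_seed(15)
  rpkm <- exp(stats::rnorm(3000, 2, 1))
  gc <- stats::runif(3000, 0.3, 0.7)
  res <- define_de(mk_table(rpkm, rpkm * exp(stats::rnorm(3000, 0, 0.05)), gc),
                   "A", "B", fdr = 0.001)
  expect_equal(sum(res$call != "ns"), 0)
  expect_true(all(res$q >= res$p, na.rm = TRUE))
})

test_that("define_de is symmetric under sample swap and monotone in FDR", {
  sim <- simulate_counts(n_genes = 3000, n_de = 60, seed = 21)
  r_ab <- define_de(sim$table, "A", "B")
  r_ba <- define_de(sim$table, "B", "A")
  # swapping samples flips fold-change sign and up/down labels (pseudocounts
  # make the symmetry approximate at very low expression)
  hi <- rowSums(sim$table$counts >= 10) == 2
  expect_equal(r_ab$log2_fc[hi], -r_ba$log2_fc[hi], tolerance = 0.02)
  expect_equal(sum(r_ab$call == "up"), sum(r_ba$call == "down"), tolerance = 2)
  agree <- mean((r_ab$call == "up") == (r_ba$call == "down"))
  expect_gte(agree, 0.99)
  # lowering the threshold never adds calls
  strict <- define_de(sim$table, "A", "B", fdr = 1e-5)
  expect_true(all(strict[call != "ns", gene_id] %in% r_ab[call != "ns", gene_id]))
})

test_that("null comparisons stay within the binomial call budget", {
  # no planted effects: calls at FDR 0.001 should be rare
  sim <- simulate_counts(n_genes = 10000, n_de = 0, seed = 31)
  res <- define_de(sim$table, "A", "B", fdr = 0.001)
  expect_lte(sum(res$call != "ns"), stats::qbinom(0.99, 10000, 0.001) + 3)
})

test_that("gene ordering does not affect the calls", {
  sim <- simulate_counts(n_genes = 2000, n_de = 40, seed = 41)
  res1 <- define_de(sim$table, "A", "B")
  perm <- withr::with_seed(1, sample(2000))
  tbl2 <- expression_table(sim$table$gene_id[perm], sim$table$counts[perm, ],
                           sim$table$rpkm[perm, ], sim$table$gc_fraction[perm],
                           sim$table$length_bp[perm])
  res2 <- define_de(tbl2, "A", "B")
  m <- match(res1$gene_id, res2$gene_id)
  expect_equal(res1$call, res2$call[m])
  expect_equal(res1$z, res2$z[m], tolerance = 1e-10)
})
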