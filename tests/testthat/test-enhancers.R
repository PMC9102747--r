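mk_flat_track <- function(bins_val, n_bins = 1000, bw = 100, depth = NULL) {
  signal_track(list(chr1 = rep(bins_val, n_bins)), bw,
               c(chr1 = n_bins * bw), depth = depth)
}

test_that("quantile_normalize matches its definition and preserves ranks", {
  withr::local_seed(80)
  m <- matrix(stats::rexp(400), 100, 4, dimnames = list(NULL, letters[1:4]))
  qn <- quantile_normalize(m)
  ref <- rowMeans(apply(m, 2, sort))
  for (j in 1:4) {
    expect_equal(sort(qn[, j]), ref, tolerance = 1e-12)
    expect_equal(rank(qn[, j]), rank(m[, j]))
  }
  # identical columns unchanged
  mi <- cbind(a = m[, 1], b = m[, 1])
  expect_equal(quantile_normalize(mi), mi)
  # permuted columns end up with identical multisets
  mp <- cbind(a = m[, 1], b = sample(m[, 1]))
  qp <- quantile_normalize(mp)
  expect_equal(sort(qp[, 1]), sort(qp[, 2]))
})

test_that("quantile_normalize agrees with the limma implementation", {
  skip_if_not_installed("limma")
  withr::local_seed(81)
  m <- matrix(stats::rgamma(600, 2), 150, 4)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)), tolerance = 1e-10)
})

test_that("the catalogue discards TSS-overlapping regions and applies the tag floor", {
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chr1", strand = "+", tss = 50000,
    start = 50000, end = 55000, gc_fraction = 0.5, biotype = "protein_coding")
  # region straddling the TSS window [48000, 52000) by a single bp
  peaks <- list(
    A = gintervals("chr1", c(10000, 47000), c(12000, 48001)),
    B = gintervals("chr1", c(10000, 20000), c(12000, 22000)))
  tr <- list(A = mk_flat_track(10), B = mk_flat_track(10))
  cat_ <- build_catalogue(peaks, tr, genes, tag_min = 40, seed = 1)
  # flat track: 10 tags per 100-bp bin = 200 tags on 2 Kb regions
  expect_false(any(overlaps_any(cat_$regions,
                                gintervals("chr1", 48000, 52000))))
  expect_true(all(cat_$regions$start %in% c(10000, 20000)))
})

test_that("tags exactly at the floor are dropped; 41 passes", {
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chr1", strand = "+", tss = 90000,
    start = 90000, end = 95000, gc_fraction = 0.5, biotype = "protein_coding")
  bins <- rep(0, 1000)
  bins[101:120] <- 2     # region 1: [10000, 12000) -> 40 tags
  bins[301:320] <- 2.05  # region 2: [30000, 32000) -> 41 tags
  tr <- signal_track(list(chr1 = bins), 100, c(chr1 = 1e5))
  peaks <- list(A = gintervals("chr1", c(10000, 30000), c(12000, 32000)),
                B = gintervals("chr1", c(10000, 30000), c(12000, 32000)))
  cat_ <- build_catalogue(peaks, list(A = tr, B = tr), genes, seed = 1)
  expect_equal(cat_$regions$start, 30000)   # strict > 40
})

test_that("state classification is strict at the signal thresholds", {
  cat_ <- list(signal = cbind(A = c(0, 25, 25.01), B = c(30, 0, 0)),
               signal_k4me1 = cbind(A = c(40, 40.5, 0), B = c(0, 0, 0)),
               cell_types = c("A", "B"))
  st <- classify_states(cat_)
  expect_equal(unname(st[, "A"]), c("none", "primed", "active"))
  expect_equal(unname(st[, "B"]), c("active", "none", "none"))
  counts <- attr(st, "counts")
  expect_equal(counts["active", "A"], 1)
})

test_that("gain/loss tracing against a reference cell type", {
  st <- rbind(c("active", "active"), c("primed", "none"), c("none", "active"))
  colnames(st) <- c("ref", "tgt")
  gl <- trace_gain_loss(st, "ref")
  expect_equal(gl[cell_type == "ref", total_gained], 0)
  expect_equal(gl[cell_type == "tgt", total_gained], 1)
  expect_equal(gl[cell_type == "tgt", total_lost], 1)
  expect_equal(gl[cell_type == "tgt", active_gained], 1)
  expect_equal(gl[cell_type == "tgt", active_lost], 0)
})

test_that("provenance percentages cover the trivial cases", {
  st <- matrix("active", 3, 3, dimnames = list(NULL, c("M", "ref", "P")))
  pv <- provenance_fraction(st, "M", "ref", "P")
  expect_equal(pv$in_reference, 100)
  expect_equal(pv$unique, 0)
  st2 <- st; st2[, c("ref", "P")] <- "none"
  pv2 <- provenance_fraction(st2, "M", "ref", "P")
  expect_equal(pv2$unique, 100)
})

test_that("super-enhancer cutoff: linear ramp, scale invariance, degenerate cases", {
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chr1", strand = "+", tss = 95000,
    start = 95000, end = 99000, gc_fraction = 0.5, biotype = "protein_coding")
  # 21 isolated regions (spacing > stitch gap) with a linear signal ramp
  n <- 21
  starts <- seq(0, by = 4000, length.out = n)
  bins <- rep(0, 3000)
  for (i in seq_len(n)) {
    bins[(starts[i] / 100 + 1):(starts[i] / 100 + 10)] <- i   # 10i tags each
  }
  tr <- signal_track(list(chr1 = bins), 100, c(chr1 = 3e5))
  peaks <- gintervals("chr1", starts, starts + 1000)
  se <- call_super_enhancers(peaks, tr, genes, stitch_gap = 2000)
  expect_equal(nrow(se), n)
  # linear ramp: tangent is flat, cutoff at the curve midpoint
  expect_equal(sum(se$super), (n - 1) / 2)
  expect_true(attr(se, "degenerate"))
  # scale invariance: scaling the track leaves the super set unchanged
  tr10 <- signal_track(list(chr1 = bins * 10), 100, c(chr1 = 3e5))
  se10 <- call_super_enhancers(peaks, tr10, genes, stitch_gap = 2000)
  expect_equal(se10$super, se$super)
  # single region: sole candidate, flagged
  se1 <- call_super_enhancers(peaks[1], tr, genes, stitch_gap = 2000)
  expect_true(attr(se1, "degenerate"))
  expect_equal(nrow(se1), 1)
})

test_that("a convex signal curve puts only the high plateau above the cutoff", {
  genes <- data.table::data.table(
    gene_id = "g1", chrom = "chr1", strand = "+", tss = 295000,
    start = 295000, end = 299000, gc_fraction = 0.5, biotype = "protein_coding")
  n <- 50
  starts <- seq(0, by = 5000, length.out = n)
  sig <- c(rep(1, 45), c(40, 50, 60, 70, 80))   # tags per bin over 10 bins
  bins <- rep(0, 3000)
  for (i in seq_len(n)) {
    bins[(starts[i] / 100 + 1):(starts[i] / 100 + 10)] <- sig[i]
  }
  tr <- signal_track(list(chr1 = bins), 100, c(chr1 = 3e5))
  se <- call_super_enhancers(gintervals("chr1", starts, starts + 1000), tr,
                             genes, stitch_gap = 2000)
  expect_equal(sum(se$super), 5)
  expect_false(attr(se, "degenerate"))
})

test_that("gene association keeps <=50 Kb promoters, ties to smaller gene id", {
  genes <- data.table::data.table(
    gene_id = c("gB", "gA", "gC"), chrom = "chr1", strand = "+",
    tss = c(149000, 151000, 202000),
    start = c(149000, 151000, 202000), end = c(152000, 154000, 205000),
    gc_fraction = 0.5, biotype = "protein_coding")
  regions <- data.table::data.table(region_id = c("near", "far"),
                                    chrom = "chr1",
                                    start = c(100000, 253000),
                                    end = c(101000, 254000))
  assoc <- associate_genes(regions, genes, max_dist = 50000)
  # "near" [100000,101000): gB at 48 Kb, gA at 50 Kb -> kept, nearest gB
  expect_equal(assoc[region_id == "near", gene_id], "gB")
  # "far" [253000,254000): nearest TSS 202000 at 51 Kb -> dropped
  expect_false("far" %in% assoc$region_id)
  # equidistant tie breaks toward the smaller gene id
  mid <- data.table::data.table(region_id = "mid", chrom = "chr1",
                                start = 149900, end = 150101)
  expect_equal(associate_genes(mid, genes)$gene_id, "gA")
})

test_that("gene association equals a brute-force nearest search", {
  withr::local_seed(82)
  genes <- data.table::data.table(
    gene_id = sprintf("g%03d", 1:40), chrom = "chr1", strand = "+",
    tss = sort(sample.int(1e6, 40)), gc_fraction = 0.5,
    biotype = "protein_coding")
  genes[, start := tss][, end := tss + 1000]
  s <- sort(sample.int(1e6 - 2000, 30))
  regions <- data.table::data.table(region_id = sprintf("r%02d", 1:30),
                                    chrom = "chr1", start = s, end = s + 1500)
  assoc <- associate_genes(regions, genes, max_dist = 5e4)
  for (k in seq_len(nrow(regions))) {
    d <- pmax(0, pmax(genes$tss - regions$end[k] + 1,
                      regions$start[k] - genes$tss))
    if (min(d) > 5e4) {
      expect_false(regions$region_id[k] %in% assoc$region_id)
    } else {
      cand <- genes$gene_id[d == min(d)]
      expect_equal(assoc[region_id == regions$region_id[k], gene_id],
                   sort(cand)[1])
    }
  }
})

test_that("enhancer methylation contrast recovers a planted depression", {
  withr::local_seed(83)
  regions <- data.table::data.table(region_id = c("r1", "r2"), chrom = "chr1",
                                    start = c(1000, 9000), end = c(3000, 11000))
  cat_ <- list(regions = regions)
  class(cat_) <- "enhancer_catalogue"
  pos <- sort(sample(1000:11000, 400))
  mk <- function(mu) data.table::data.table(
    chrom = "chr1", pos = pos,
    fraction = pmin(pmax(mu + stats::rnorm(length(pos), 0, 0.02), 0), 1))
  me <- methylation_at_enhancers(list(P = mk(0.8), M = mk(0.5)), cat_,
                                 c("r1", "r2"), group_a = "P", group_b = "M")
  expect_equal(me$delta_mean, 0.3, tolerance = 0.03)
  expect_lt(me$test$p.value, 1e-10)
  expect_error(methylation_at_enhancers(list(P = mk(0.8), M = mk(0.5)), cat_,
                                        "absent", "P", "M"), "no regions")
})
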