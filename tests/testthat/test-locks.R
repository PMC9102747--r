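test_that("a hand-constructed peak train yields exactly one LOCK", {
  # 20 peaks of 5 Kb spaced 1 Kb apart span 119 Kb; two distant singleton
  # peaks give background gaps ~2 Mb. The chromosome-wise log-gap threshold
  # is exp(median + 1.5 IQR) = 1000 (19 of 21 gaps are exactly 1000), so the
  # train stitches and the singletons cannot form clusters.
  starts <- seq(0, by = 6000, length.out = 20)
  peaks <- gintervals("chr1", c(starts, 2e6, 4e6), c(starts + 5000, 2e6 + 5000, 4e6 + 5000))
  lk <- call_locks(peaks)
  expect_equal(nrow(lk), 1)
  expect_equal(lk$start, 0)
  expect_equal(lk$end, 119000)
  expect_equal(lk$n_peaks, 20)
})

test_that("peaks below MinLength give an empty LOCK set", {
  peaks <- gintervals("chr1", seq(0, 1e5, by = 1000), seq(0, 1e5, by = 1000) + 500)
  expect_warning(lk <- call_locks(peaks), "MinLength")
  expect_equal(nrow(lk), 0)
})

test_that("call_locks output satisfies the LOCK invariants on random input", {
  withr::local_seed(50)
  for (rep in 1:5) {
    n <- 300
    s <- sort(sample.int(5e6, n))
    peaks <- data.table::data.table(chrom = sample(c("chr1", "chr2"), n, TRUE),
                                    start = s, end = s + sample(500:20000, n, TRUE))
    lk <- suppressWarnings(call_locks(peaks))
    if (nrow(lk) == 0) next
    expect_true(all(lk$end - lk$start >= 1e5))
    expect_true(all(lk$n_peaks >= 2))
    # disjoint within chromosome
    for (ch in unique(lk$chrom)) {
      l <- lk[chrom == ch]
      if (nrow(l) > 1) expect_true(all(l$start[-1] >= l$end[-nrow(l)]))
    }
  }
})

test_that("compare_locks on identical and disjoint sets", {
  lk <- data.table::data.table(chrom = "chr1", start = c(0, 5e5),
                               end = c(2e5, 8e5), lock_id = c("a", "b"))
  cmp <- compare_locks(lk, list(same = lk))
  expect_equal(cmp$summary$retained_frac, 1)
  expect_equal(cmp$summary$lost, 0)
  far <- data.table::data.table(chrom = "chr1", start = 2e6, end = 2.2e6,
                                lock_id = "c")
  cmp2 <- compare_locks(lk, list(far = far))
  expect_equal(cmp2$summary$retained_frac, 0)
  expect_equal(cmp2$summary$lost, 2)
  # categories partition the reference set
  expect_equal(cmp2$summary$retained + cmp2$summary$lost, nrow(lk))
})

test_that("contraction_stats trivial geometries", {
  locks <- data.table::data.table(chrom = "chr1", start = c(0, 5e5),
                                  end = c(2e5, 8e5), lock_id = c("a", "b"))
  full <- locks[, .(chrom, start, end)]
  cs <- contraction_stats(locks, list(x = full))
  expect_equal(cs$segments$width, c(2e5, 3e5))
  expect_equal(sum(cs$per_lock$marked_bp), 5e5)
  none <- data.table::data.table(chrom = "chr1", start = 3e6, end = 3.1e6)
  cs0 <- contraction_stats(locks, list(x = none))
  expect_equal(sum(cs0$per_lock$marked_bp), 0)
})

test_that("lad_overlap trivial geometries", {
  locks <- data.table::data.table(chrom = "chr1", start = c(0, 5e5),
                                  end = c(2e5, 8e5), lock_id = c("a", "b"))
  expect_equal(lad_overlap(locks, locks[, .(chrom, start, end)])$lock_frac, 1)
  expect_equal(lad_overlap(locks, locks[, .(chrom, start, end)])$bp_frac, 1)
  far <- data.table::data.table(chrom = "chr1", start = 2e6, end = 3e6)
  expect_equal(lad_overlap(locks, far)$lock_frac, 0)
})

test_that("co_occupancy separates inside from outside occupancy", {
  locks <- data.table::data.table(chrom = "chr1", start = 0, end = 1e5,
                                  lock_id = "a")
  k27 <- gintervals("chr1", c(1e4, 2e4, 5e5, 6e5),
                    c(1e4 + 5000, 2e4 + 5000, 5e5 + 5000, 6e5 + 5000))
  # K9 identical to K27: each region's occupancy equals its width
  r1 <- co_occupancy(locks, k27, k27)
  expect_equal(r1$mean_inside / r1$mean_outside, 1)
  # K9 only inside the LOCK
  k9_in <- gintervals("chr1", c(1e4, 2e4), c(1e4 + 5000, 2e4 + 5000))
  r2 <- co_occupancy(locks, k9_in, k27)
  expect_equal(r2$mean_outside, 0)
  expect_gt(r2$mean_inside, 0)
})

test_that("methylation pooling and contrasts behave on controlled input", {
  m <- data.table::data.table(chrom = "chr1", pos = seq(0, 9990, by = 10),
                              fraction = 0.8)
  regions <- gintervals("chr1", 0, 5000)
  v <- methylation_in_regions(m, regions)
  expect_equal(length(v), 500)
  expect_error(methylation_in_regions(m, regions[0]), "empty region set")
  m2 <- data.table::copy(m)
  withr::local_seed(60)
  m$fraction <- pmin(pmax(0.8 + stats::rnorm(nrow(m), 0, 0.02), 0), 1)
  m2$fraction <- pmin(pmax(0.6 + stats::rnorm(nrow(m), 0, 0.02), 0), 1)
  mt <- methylation_test(m, m2, regions)
  expect_equal(mt$delta_mean, 0.2, tolerance = 0.01)
  expect_lt(mt$test$p.value, 1e-10)
})

test_that("marked fraction and large-region counts match the bitmap oracle", {
  expect_equal(marked_genome_fraction(gintervals("chr1", 0, 100)[0], 1000), 0)
  whole <- gintervals("chr1", 0, 1e6)
  expect_equal(marked_genome_fraction(whole, 1e6), 1)
  expect_equal(large_region_count(whole, 1e5), 1)
  withr::local_seed(61)
  x <- random_intervals(200, 5000)
  expect_equal(marked_genome_fraction(x, 5000),
               oracle_covered_bp(x$start, x$end, 5000) / 5000)
  expect_equal(large_region_count(x, 40), sum(x$end - x$start >= 40))
})

test_that("LOCK group intersection re-applies the width filter", {
  a <- data.table::data.table(chrom = "chr1", start = 0, end = 3e5)
  b <- data.table::data.table(chrom = "chr1", start = 2.5e5, end = 6e5)
  i1 <- locks_intersection(list(a, b))
  expect_equal(nrow(i1), 0)    # 50 Kb intersection < 100 Kb
  b2 <- data.table::data.table(chrom = "chr1", start = 1e5, end = 6e5)
  i2 <- locks_intersection(list(a, b2))
  expect_equal(i2[, .(start, end)], data.table::data.table(start = 1e5, end = 3e5))
})
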