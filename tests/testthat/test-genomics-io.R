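test_that("read_bed validates and normalizes input", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("track name=x", "1\t0\t100\tpeak1", "chr2\t50\t60\tpeak2"), f)
  x <- read_bed(f)
  expect_equal(nrow(x), 2)
  expect_equal(x$chrom, c("chr1", "chr2"))   # "1" dialect normalized
  expect_equal(x$end[1] - x$start[1], 100)

  writeLines(c("chr1\t0\t100", "chr1\t5\t5"), f)
  expect_error(read_bed(f), "line 2")
  writeLines(c("chr1\t0"), f)
  expect_error(read_bed(f), "line 1")
})

test_that("BED writing round-trips through the reader", {
  withr::local_seed(42)
  x <- random_intervals(1000, 1e6, max_width = 500)
  x[, id := sprintf("iv_%04d", .I)]
  x <- sort_intervals(x)
  f <- withr::local_tempfile(fileext = ".bed")
  write_bed(x, f)
  y <- read_bed(f)
  expect_equal(y[, .(chrom, start, end, id)], x[, .(chrom, start, end, id)])
  # byte-identical on rewrite
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(y, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("merge_intervals handles book-ended, gapped and random input", {
  x <- gintervals("chr1", c(0, 10), c(10, 20))
  expect_equal(merge_intervals(x, max_gap = 0),
               data.table::data.table(chrom = "chr1", start = 0, end = 20))
  y <- gintervals("chr1", c(0, 15), c(10, 20))
  expect_equal(nrow(merge_intervals(y, max_gap = 4)), 2)   # gap 5 > 4
  expect_equal(nrow(merge_intervals(y, max_gap = 5)), 1)
  expect_error(merge_intervals(y, max_gap = -1), "non-negative")

  withr::local_seed(1)
  for (rep in 1:5) {
    x <- random_intervals(500, 5000)
    m <- merge_intervals(x)
    expect_equal(total_bp(m), oracle_covered_bp(x$start, x$end, 5000))
    # disjoint and sorted
    expect_true(all(diff(m$start) > 0))
    expect_true(all(m$start[-1] > m$end[-nrow(m)]))
    # idempotent
    expect_equal(merge_intervals(m), m)
  }
})

test_that("coverage_fraction matches the per-base oracle", {
  tgt <- gintervals("chr1", 0, 100)
  expect_equal(coverage_fraction(tgt, gintervals("chr1", 0, 50)), 0.5)
  expect_equal(coverage_fraction(tgt, gintervals("chr1", 200, 300)), 0)

  withr::local_seed(2)
  for (rep in 1:10) {
    set <- random_intervals(50, 2000)
    tgt <- random_intervals(20, 2000, max_width = 200)
    got <- coverage_fraction(tgt, set)
    exp <- vapply(seq_len(nrow(tgt)), function(i) {
      oracle_overlap_bp(tgt$start[i], tgt$end[i], set$start, set$end, 2000) /
        (tgt$end[i] - tgt$start[i])
    }, numeric(1))
    expect_equal(got, exp)
  }
})

test_that("interval algebra agrees with IRanges on random instances", {
  skip_if_not_installed("IRanges")
  withr::local_seed(3)
  x <- random_intervals(300, 10000)
  m <- merge_intervals(x)
  ir <- IRanges::reduce(IRanges::IRanges(x$start + 1, x$end))
  expect_equal(m$start, IRanges::start(ir) - 1)
  expect_equal(m$end, IRanges::end(ir))
  y <- random_intervals(300, 10000)
  got <- intersect_intervals(x, y)
  iri <- IRanges::intersect(IRanges::IRanges(x$start + 1, x$end),
                            IRanges::IRanges(y$start + 1, y$end))
  expect_equal(got$start, IRanges::start(iri) - 1)
  expect_equal(got$end, IRanges::end(iri))
})

test_that("region_tag_count pro-rates bins and matches per-base accumulation", {
  tr <- signal_track(list(chr1 = rep(1, 100)), 10, c(chr1 = 1000))
  expect_equal(region_tag_count(tr, gintervals("chr1", 0, 100)), 10)
  expect_equal(region_tag_count(tr, gintervals("chr1", 5, 15)), 1)  # half + half
  empty <- signal_track(list(chr1 = rep(0, 100)), 10, c(chr1 = 1000))
  expect_equal(region_tag_count(empty, gintervals("chr1", 0, 500)), 0)
  expect_error(region_tag_count(tr, gintervals("chr1", 900, 1100)), "off-chromosome")

  withr::local_seed(4)
  for (rep in 1:10) {
    bins <- stats::rpois(100, 3)
    tr <- signal_track(list(chr1 = bins), 7, c(chr1 = 700))
    reg <- random_intervals(20, 700, max_width = 100)
    got <- region_tag_count(tr, reg)
    exp <- vapply(seq_len(nrow(reg)), function(i) {
      oracle_tag_count(bins, 7, reg$start[i], reg$end[i])
    }, numeric(1))
    expect_equal(got, exp, tolerance = 1e-9)
  }
})

test_that("normalized density scales to enriched-tag total per Kb", {
  tr <- signal_track(list(chr1 = rep(2, 100)), 10, c(chr1 = 1000))
  # region of 500 bp holds 100 tags -> 200 tags/Kb; per 1e7 enriched tags
  d <- normalized_density(tr, gintervals("chr1", 0, 500),
                          within_enriched_total = 1e7)
  expect_equal(d, 200)
  expect_error(normalized_density(tr, gintervals("chr1", 0, 10), 0), "positive")
})

test_that("wiggle and bedGraph readers produce equivalent tracks", {
  f <- withr::local_tempfile(fileext = ".wig")
  writeLines(c("fixedStep chrom=1 start=11 step=10 span=10",
               "1", "2", "3",
               "variableStep chrom=chr2 span=5",
               "101 7"), f)
  w <- read_wiggle(f)
  expect_equal(w$start, c(10, 20, 30, 100))   # converted to 0-based
  expect_equal(w$chrom, c("chr1", "chr1", "chr1", "chr2"))
  expect_equal(w$value, c(1, 2, 3, 7))

  g <- withr::local_tempfile(fileext = ".bedgraph")
  write_bedgraph(w[chrom == "chr1"], g)
  expect_equal(read_bedgraph(g)$value, c(1, 2, 3))
  tr <- bedgraph_to_track(w[chrom == "chr1"], 10, c(chr1 = 100))
  expect_equal(region_tag_count(tr, gintervals("chr1", 10, 40)), 6)
})

test_that("gene annotation and methylation readers validate content", {
  g <- data.table::data.table(
    gene_id = c("g1", "g2"), chrom = c("chr1", "chr1"),
    strand = c("+", "-"), tss = c(100, 900), start = c(100, 500),
    end = c(400, 900), gc_fraction = c(0.4, 0.6),
    biotype = "protein_coding")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_gene_annotation(g, f)
  expect_equal(read_gene_annotation(f)$gene_id, c("g1", "g2"))
  g_bad <- data.table::copy(g); g_bad$tss[1] <- 150
  write_gene_annotation(g_bad, f)
  expect_error(read_gene_annotation(f), "TSS inconsistent")

  m <- data.table::data.table(chrom = "chr1", pos = c(10, 50),
                              fraction = c(0.5, 0.9), coverage = c(10L, 20L))
  fm <- withr::local_tempfile(fileext = ".bedgraph")
  write_methyl_bedgraph(m, fm)
  m2 <- read_methyl_bedgraph(fm)
  expect_equal(m2$fraction, c(0.5, 0.9))
  expect_equal(m2$pos, c(10, 50))
})
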