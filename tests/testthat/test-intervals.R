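test_that("make_windows tiles, truncates and overlaps as specified", {
  lay <- genome_layout(c(chr1 = 2500))
  w <- make_windows(lay, 1000, 1000)
  expect_equal(start(w) - 1L, c(0L, 1000L, 2000L))
  expect_equal(end(w), c(1000L, 2000L, 2500L))

  w <- make_windows(genome_layout(c(chr1 = 2000)), 1000, 800)
  expect_equal(start(w) - 1L, c(0L, 800L, 1600L))
  expect_equal(end(w), c(1000L, 1800L, 2000L))

  w <- make_windows(genome_layout(c(chr1 = 500)), 1000, 1000)
  expect_equal(c(start(w) - 1L, end(w)), c(0L, 500L))

  expect_error(make_windows(lay, 1000, 1200), "step")
  expect_error(make_windows(lay, 0, 0))
})

test_that("non-overlapping windows partition each chromosome exactly", {
  lay <- genome_layout(c(a = 10000, b = 3701))
  w <- make_windows(lay, 1000, 1000)
  for (chr in names(lay)) {
    wc <- w[as.character(seqnames(w)) == chr]
    expect_equal(sum(width(wc)), as.numeric(lay[[chr]]))
    expect_equal(length(merge_intervals(wc)), 1L)  # full cover, no gaps
  }
})

test_that("merge_intervals fuses overlaps and bookends and is idempotent", {
  m <- merge_intervals(gr1(c(0, 5), c(10, 15)))
  expect_equal(c(start(m) - 1L, end(m)), c(0L, 15L))
  m <- merge_intervals(gr1(c(0, 10), c(10, 20)))
  expect_equal(c(start(m) - 1L, end(m)), c(0L, 20L))
  expect_equal(length(merge_intervals(GRanges())), 0L)

  set.seed(7)
  x <- random_interval_set(200, 10000)
  m <- merge_intervals(gr1(x$start, x$end))
  expect_identical(merge_intervals(m), m)
  expect_lte(total_bases(m), sum(x$end - x$start))
  oracle <- runs_from_mask(mask_from_intervals(x$start, x$end, 10000))
  expect_equal(start(m) - 1L, oracle$start)
  expect_equal(end(m), oracle$end)
})

test_that("intersect_sets reports overlapping features and overlap bases", {
  r <- intersect_sets(gr1(0, 10), gr1(5, 6))
  expect_equal(r$n_features, 1L)
  expect_equal(r$overlap_bases, 1)
  r <- intersect_sets(gr1(0, 10), gr1(20, 30))
  expect_equal(r$n_features, 0L)
  expect_equal(r$overlap_bases, 0)

  set.seed(11)
  for (rep in 1:5) {
    a <- random_interval_set(40, 5000)
    b <- random_interval_set(40, 5000)
    res <- intersect_sets(gr1(a$start, a$end), gr1(b$start, b$end))
    ma <- mask_from_intervals(a$start, a$end, 5000)
    mb <- mask_from_intervals(b$start, b$end, 5000)
    expect_equal(res$overlap_bases, sum(ma & mb))
    hit <- vapply(seq_len(nrow(a)), function(i)
      any(mb[(a$start[i] + 1):a$end[i]]), NA)
    expect_equal(res$n_features, sum(hit))
    # symmetry of overlap bases
    expect_equal(intersect_sets(gr1(b$start, b$end), gr1(a$start, a$end))$overlap_bases,
                 res$overlap_bases)
  }
})

test_that("remove_gap_windows drops any-overlap windows, keeps bookended", {
  w <- gr1(c(0, 1000), c(1000, 2000))
  expect_equal(length(remove_gap_windows(w, gr1(999, 1001))), 0L)
  kept <- remove_gap_windows(gr1(0, 1000), gr1(1000, 1005))
  expect_equal(length(kept), 1L)

  set.seed(3)
  w <- make_windows(genome_layout(c(chr1 = 20000)), 1000, 1000)
  g <- random_interval_set(15, 20000)
  kept <- remove_gap_windows(w, gr1(g$start, g$end))
  gm <- mask_from_intervals(g$start, g$end, 20000)
  keep_oracle <- vapply(seq_along(w), function(i)
    !any(gm[start(w)[i]:end(w)[i]]), NA)
  expect_equal(length(kept), sum(keep_oracle))
})

test_that("fragment_depth matches per-base counting and conserves mass", {
  lay <- genome_layout(c(chr1 = 30))
  d <- fragment_depth(gr1(c(0, 5), c(10, 15)), lay)
  v <- as.integer(d[["chr1"]])
  expect_equal(v, c(rep(1L, 5), rep(2L, 5), rep(1L, 5), rep(0L, 15)))
  expect_equal(as.integer(fragment_depth(GRanges(), lay)[["chr1"]]), rep(0L, 30))

  set.seed(5)
  lay <- genome_layout(c(chr1 = 20000))
  x <- random_interval_set(1000, 20000)
  d <- as.integer(fragment_depth(gr1(x$start, x$end), lay)[["chr1"]])
  expect_equal(d, depth_from_intervals(x$start, x$end, 20000))
  expect_equal(sum(d), sum(x$end - x$start))  # mass conservation

  expect_error(fragment_depth(gr1(19900, 20100), lay), "outside layout")
})

test_that("BED round-trips, preserves extra columns, rejects malformed lines", {
  f <- tempfile(fileext = ".bed")
  writeLines("chr1\t0\t100", f)
  gr <- read_bed(f)
  expect_equal(c(start(gr) - 1L, end(gr)), c(0L, 100L))

  writeLines(c("chr1\t0\t100", "chr1\t100\t100"), f)
  expect_error(read_bed(f), "line 2")
  writeLines("chr1\tzero\t100", f)
  expect_error(read_bed(f), "non-integer")

  writeLines(c("chr1\t5\t10\tfeatA\t3", "chr2\t0\t2\tfeatB\t7"), f)
  gr <- read_bed(f)
  expect_equal(mcols(gr)$name, c("featA", "featB"))

  set.seed(9)
  x <- random_interval_set(100, 50000)
  gr <- GenomicRanges::sort(gr1(x$start, x$end))
  write_bed(gr, f)
  back <- read_bed(f)
  expect_equal(start(back), start(gr))
  expect_equal(end(back), end(gr))
  f2 <- tempfile(fileext = ".bed")
  write_bed(back, f2)
  expect_identical(readLines(f), readLines(f2))  # canonical idempotence
})

test_that("genome_layout validates its invariants", {
  expect_error(genome_layout(c(chr1 = 0)), "positive")
  expect_error(genome_layout(c(chr1 = 10, chr1 = 20)), "duplicated")
  expect_error(genome_layout(c(10, 20)), "name")
  lay <- genome_layout(c(chr1 = 10, chr2 = 20))
  expect_equal(layout_size(lay), 30)
  f <- tempfile()
  write_chrom_sizes(lay, f)
  expect_equal(layout_size(read_chrom_sizes(f)), 30)
})
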