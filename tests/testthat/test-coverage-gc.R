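test_that("window medians equal a sort-based per-window oracle", {
  lay <- genome_layout(c(chr1 = 4))
  d <- fragment_depth(gr1(c(0, 1, 2, 3), c(4, 4, 4, 4)), lay)
  wc <- window_median_coverage(d, gr1(0, 4))
  expect_equal(wc$median_cov, 2.5)  # depths 1,2,3,4

  lay <- genome_layout(c(chr1 = 100))
  wc <- window_median_coverage(fragment_depth(GRanges(), lay), gr1(0, 100))
  expect_equal(wc$median_cov, 0)

  set.seed(21)
  lay <- genome_layout(c(chr1 = 8000))
  x <- random_interval_set(400, 8000)
  dep <- fragment_depth(gr1(x$start, x$end), lay)
  w <- make_windows(lay, 1000, 1000)
  wc <- window_median_coverage(dep, w)
  oracle <- depth_from_intervals(x$start, x$end, 8000)
  for (i in seq_along(w)) {
    expect_equal(wc$median_cov[i],
                 stats::median(oracle[start(w)[i]:end(w)[i]]))
  }
})

test_that("gc_percent excludes ambiguous bases from the denominator", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACGTAAAAGCGCACGN"))
  w <- gr1(c(0, 4, 8, 12, 12), c(4, 8, 12, 16, 15))
  # "ACGN": N drops from the denominator, so 2 GC of 3 unambiguous = 67
  expect_equal(gc_percent(g, w), c(50L, 0L, 100L, 67L, 67L))
  gn <- Biostrings::DNAStringSet(c(chr1 = "NNNN"))
  expect_true(is.na(gc_percent(gn, gr1(0, 4))))
})

test_that("GC model reproduces the median-ratio definition", {
  # single GC bin: factor 1, normalization is the identity
  wc <- data.frame(median_cov = rep(c(10, 20, 30), 20), gc_pct = 40L)
  m <- fit_gc_model(wc, min_bin_windows = 10)
  expect_equal(m$global_median, 20)
  expect_equal(m$bins$factor, 1)
  expect_equal(gc_normalize(wc, m)$norm_cov, wc$median_cov)

  # factor is global median / bin median
  wc <- data.frame(median_cov = c(rep(41, 60), rep(20.5, 60)),
                   gc_pct = rep(c(40L, 70L), each = 60))
  m <- fit_gc_model(wc, min_bin_windows = 50)
  expect_equal(m$global_median, stats::median(wc$median_cov))
  f70 <- m$bins$factor[m$bins$gc_pct == 70]
  expect_equal(f70 * 20.5, m$global_median)

  # small or zero bins are left uncorrected
  wc <- data.frame(median_cov = c(rep(40, 60), rep(0, 60), 10),
                   gc_pct = rep(c(50L, 60L, 90L), c(60, 60, 1)))
  m <- fit_gc_model(wc, min_bin_windows = 50)
  expect_equal(m$bins$factor[m$bins$gc_pct == 60], 1)  # zero median
  expect_equal(m$bins$factor[m$bins$gc_pct == 90], 1)  # too few windows

  expect_error(fit_gc_model(data.frame(median_cov = 0, gc_pct = 50L)),
               "degenerate")
})

test_that("GC normalization fixed point: usable bin medians all equal global", {
  # simulate a GC response curve directly on window medians
  set.seed(31)
  gc <- sample(c(25L, 50L, 65L), 3000, replace = TRUE)
  response <- c(`25` = 0.5, `50` = 1.0, `65` = 0.7)
  med <- round(40 * response[as.character(gc)] + rnorm(3000, 0, 2), 1)
  wc <- data.frame(median_cov = pmax(med, 0), gc_pct = gc)
  m <- fit_gc_model(wc)
  wc <- gc_normalize(wc, m)
  for (g in m$bins$gc_pct[m$bins$usable]) {
    expect_equal(stats::median(wc$norm_cov[wc$gc_pct == g]), m$global_median)
  }
  # normalization preserves the global median when all bins usable
  expect_equal(stats::median(wc$norm_cov), m$global_median)
})

test_that("robust_normal stores symmetric k-SD cutoffs", {
  m <- robust_normal(41, 7, k = 2)
  expect_equal(m$low_cut, 27)
  expect_equal(m$high_cut, 55)
  expect_equal(m$high_cut - m$mean, m$mean - m$low_cut)
  expect_error(robust_normal(41, 0), "sd")
})

test_that("robust normal fit recovers contaminated moments", {
  set.seed(42)
  x <- rnorm(1e5, 41, 7)
  f <- fit_robust_normal(x)
  expect_lt(abs(f$mean - 41), 0.2)
  expect_lt(abs(f$sd - 7), 0.2)

  set.seed(42)
  x <- c(rnorm(98000, 41, 7), runif(2000, 200, 400))
  f <- fit_robust_normal(x)
  expect_lt(abs(f$mean - 41), 0.5)
  expect_lt(abs(f$sd - 7), 0.5)
  expect_gt(stats::sd(x), 7 * 1.5)  # the plain SD is badly inflated

  expect_error(fit_robust_normal(rnorm(50)), "100")
})

test_that("robust fit recovers within 5% across moments and contamination", {
  set.seed(1234)
  for (mu in c(20, 41, 80)) {
    for (sig in c(3, 7, 15)) {
      x <- c(rnorm(95000, mu, sig), runif(5000, mu + 10 * sig, mu + 20 * sig))
      f <- fit_robust_normal(x)
      expect_lt(abs(f$mean - mu) / mu, 0.05)
      expect_lt(abs(f$sd - sig) / sig, 0.05)
    }
  }
})

test_that("coverage labels use strict cutoffs and partition all windows", {
  m <- robust_normal(41, 7, k = 2)
  lab <- classify_coverage(c(56, 26, 27, 55, 41), m)
  expect_equal(as.character(lab), c("HIGH", "LOW", "NORMAL", "NORMAL", "NORMAL"))
  set.seed(2)
  x <- runif(500, 0, 100)
  lab <- classify_coverage(x, m)
  expect_equal(sum(table(lab)), 500)         # exactly one label each
  expect_false(any(is.na(lab)))
})

test_that("multimapper-dominated windows are flagged and merged", {
  w <- gr1(c(0, 1000, 2000), c(1000, 2000, 3000))
  rd <- fake_reads(start = c(seq(100, 950, by = 90), seq(1100, 1500, by = 100)),
                   end = c(seq(100, 950, by = 90), seq(1100, 1500, by = 100)) + 50)
  rd$mapq <- c(rep(0L, 6), rep(60L, 4), rep(60L, 5))   # window1: 6/10 mm
  mm <- multimap_windows(rd, w)
  expect_equal(mm$table$pct[1], 60)
  expect_equal(mm$table$pct[3], 0)            # no reads -> 0, not flagged
  expect_equal(length(mm$flagged), 1L)
  expect_equal(start(mm$flagged) - 1L, 0L)
})

test_that("lc_attribution reports containment and disjoint extremes", {
  lc <- gr1(c(0, 5000), c(2000, 7000))
  mm <- gr1(c(100, 5100), c(1900, 6900))
  a <- lc_attribution(lc, mm)
  expect_equal(a$pct_mm_in_lc, 100)
  expect_equal(a$pct_lc_in_mm, 100)
  b <- lc_attribution(lc, gr1(9000, 9500))
  expect_equal(b$pct_mm_in_lc, 0)
  expect_equal(b$pct_lc_in_mm, 0)
})
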