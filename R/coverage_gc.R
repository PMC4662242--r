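## Window coverage, GC normalization, robust-normal cutoffs, multimappers.

#' Median per-base fragment depth in each window
#'
#' For every window, takes the median of its per-base depth values (one
#' value per base of the window, zeros included).
#'
#' @param depth An `RleList` from [fragment_depth()].
#' @param windows `GRanges` of (gap-filtered) windows.
#' @return A `data.frame` with `chrom`, `start` (0-based), `end`,
#'   `median_cov`.
#' @export
window_median_coverage <- function(depth, windows) {
  chrs <- as.character(seqnames(windows))
  med <- numeric(length(windows))
  for (chr in unique(chrs)) {
    i <- which(chrs == chr)
    v <- Views(depth[[chr]], start = start(windows)[i], end = end(windows)[i])
    med[i] <- viewApply(v, function(x) stats::median(as.numeric(x)))
  }
  data.frame(chrom = chrs, start = start(windows) - 1L, end = end(windows),
             median_cov = med)
}

#' Integer GC percentage of assembly sequence in each window
#'
#' `100 * (G + C) / (A + C + G + T)` rounded to the nearest integer;
#' ambiguous bases (N etc.) are excluded from the denominator. A window with
#' no unambiguous base gets `NA` and is excluded from GC-model fitting.
#'
#' @param genome A [Biostrings::DNAStringSet] (names matching chromosome
#'   names) or path to a FASTA file.
#' @param windows `GRanges` of windows.
#' @return Integer vector of GC percentages (`NA` where undefined), parallel
#'   to `windows`.
#' @export
gc_percent <- function(genome, windows) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chrs <- as.character(seqnames(windows))
  out <- rep(NA_integer_, length(windows))
  for (chr in unique(chrs)) {
    i <- which(chrs == chr)
    v <- Biostrings::extractAt(genome[[chr]],
                               IRanges(start(windows)[i], end(windows)[i]))
    f <- Biostrings::letterFrequency(v, c("A", "C", "G", "T"))
    denom <- rowSums(f)
    gc <- f[, "G"] + f[, "C"]
    out[i] <- ifelse(denom == 0, NA_integer_, as.integer(round(100 * gc / denom)))
  }
  out
}

#' Fit the per-GC-bin median-ratio normalization model
#'
#' The coverage of a window is multiplied by a factor `f` equal to the
#' overall median of window medians divided by the median of all windows
#' sharing the window's integer GC percentage. Medians (not means) keep the
#' factors insensitive to extreme outliers. Bins with fewer than
#' `min_bin_windows` windows or a zero median are left uncorrected
#' (`f = 1`), as the ratio is unstable there.
#'
#' @param wc A window-coverage `data.frame` with columns `median_cov` and
#'   `gc_pct` (see [window_median_coverage()] and [gc_percent()]).
#' @param min_bin_windows Minimum windows per GC bin for a usable factor
#'   (default 50).
#' @return An object of class `gc_norm_model`: list with `global_median`
#'   and a `bins` data.frame (`gc_pct`, `bin_median`, `n_windows`,
#'   `factor`, `usable`).
#' @export
fit_gc_model <- function(wc, min_bin_windows = 50) {
  stopifnot(nrow(wc) >= 1, all(c("median_cov", "gc_pct") %in% names(wc)))
  usable_rows <- !is.na(wc$gc_pct)
  global_median <- stats::median(wc$median_cov)
  if (global_median == 0 && all(wc$median_cov == 0))
    stop("fit_gc_model: all window medians are zero (degenerate library)")
  agg <- stats::aggregate(median_cov ~ gc_pct, data = wc[usable_rows, ],
                          FUN = stats::median)
  n <- as.vector(table(wc$gc_pct[usable_rows])[as.character(agg$gc_pct)])
  usable <- n >= min_bin_windows & agg$median_cov > 0
  f <- ifelse(usable, global_median / agg$median_cov, 1)
  structure(list(global_median = global_median,
                 bins = data.frame(gc_pct = agg$gc_pct,
                                   bin_median = agg$median_cov,
                                   n_windows = n, factor = f,
                                   usable = usable)),
            class = "gc_norm_model")
}

#' @export
print.gc_norm_model <- function(x, ...) {
  cat("gc_norm_model: global median", x$global_median, "over",
      sum(x$bins$n_windows), "windows;",
      sum(x$bins$usable), "of", nrow(x$bins), "GC bins corrected\n")
  invisible(x)
}

#' Apply a GC normalization model to window coverages
#'
#' @param wc Window-coverage `data.frame` with `median_cov`, `gc_pct`.
#' @param model A [fit_gc_model()] result.
#' @return `wc` with a `norm_cov` column
#'   (`median_cov * f(gc_pct)`; windows with undefined GC keep `f = 1`).
#' @export
gc_normalize <- function(wc, model) {
  f <- rep(1, nrow(wc))
  idx <- match(wc$gc_pct, model$bins$gc_pct)
  ok <- !is.na(idx)
  f[ok] <- model$bins$factor[idx[ok]]
  wc$norm_cov <- wc$median_cov * f
  wc
}

## ---- robust normal ---------------------------------------------------------

#' Construct a robust-normal model from known moments
#'
#' Holds a mean, standard deviation and an SD multiplier `k`, with
#' symmetric cutoffs `mean - k*sd` and `mean + k*sd` used to label
#' abnormally low/high values.
#'
#' @param mean,sd Centre and spread of the central bulk (`sd > 0`).
#' @param k SD multiplier for the cutoffs (default 2).
#' @return Object of class `robust_normal` with fields `mean`, `sd`, `k`,
#'   `low_cut`, `high_cut`.
#' @examples
#' m <- robust_normal(41, 7)
#' m$low_cut   # 27
#' m$high_cut  # 55
#' @export
robust_normal <- function(mean, sd, k = 2) {
  if (!is.finite(sd) || sd <= 0) stop("robust_normal: sd must be > 0")
  structure(list(mean = mean, sd = sd, k = k,
                 low_cut = mean - k * sd, high_cut = mean + k * sd),
            class = "robust_normal")
}

#' @export
print.robust_normal <- function(x, ...) {
  cat(sprintf("robust_normal: mean %.3f, sd %.3f, k %g -> cutoffs [%.3f, %.3f]\n",
              x$mean, x$sd, x$k, x$low_cut, x$high_cut))
  invisible(x)
}

#' Fit a normal distribution to the central bulk of a sample
#'
#' Coverage distributions carry a heavy right tail (collapsed repeats,
#' mitochondrial-like sequence) that inflates the plain mean and SD. This
#' fit overlays a Gaussian on the histogram of the data and reads the
#' moments off the fitted curve, ignoring the tail: a least-squares
#' Gaussian fit (amplitude, mean, sd) to unit-width histogram bins,
#' restricted to the 5th-95th percentile range, then refit once restricted
#' to mean +/- 3 fitted SD. Deterministic.
#'
#' @param x Numeric sample (at least 100 values).
#' @param k SD multiplier for the resulting cutoffs (default 2).
#' @param binwidth Histogram bin width (default 1, i.e. integer coverage
#'   bins).
#' @return A [robust_normal()] object.
#' @export
fit_robust_normal <- function(x, k = 2, binwidth = 1) {
  x <- x[is.finite(x)]
  if (length(x) < 100) stop("fit_robust_normal: need >= 100 values")

  gauss_fit <- function(lo, hi, mu0, sd0) {
    breaks <- seq(floor(min(x) / binwidth) * binwidth,
                  ceiling(max(x) / binwidth) * binwidth + binwidth, by = binwidth)
    h <- graphics::hist(x, breaks = breaks, plot = FALSE)
    sel <- h$mids >= lo & h$mids <= hi
    d <- data.frame(m = h$mids[sel], cnt = h$counts[sel])
    if (nrow(d) < 4) stop("fit_robust_normal: too few histogram bins in range")
    fit <- try(minpack.lm::nlsLM(
      cnt ~ A * exp(-(m - mu)^2 / (2 * sigma^2)),
      data = d,
      start = list(A = max(d$cnt), mu = mu0, sigma = sd0),
      lower = c(A = 0, mu = -Inf, sigma = binwidth / 10),
      control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
    if (inherits(fit, "try-error"))
      stop("fit_robust_normal: Gaussian least-squares fit failed to converge: ",
           attr(fit, "condition")$message)
    stats::coef(fit)
  }

  q <- stats::quantile(x, c(0.05, 0.5, 0.95), names = FALSE)
  c1 <- gauss_fit(q[1], q[3], mu0 = q[2], sd0 = max((q[3] - q[1]) / 4, binwidth))
  c2 <- gauss_fit(c1[["mu"]] - 3 * abs(c1[["sigma"]]),
                  c1[["mu"]] + 3 * abs(c1[["sigma"]]),
                  mu0 = c1[["mu"]], sd0 = abs(c1[["sigma"]]))
  robust_normal(unname(c2[["mu"]]), abs(unname(c2[["sigma"]])), k = k)
}

#' Label window coverages as LOW / NORMAL / HIGH
#'
#' Strict inequalities: a value exactly at a cutoff is NORMAL.
#'
#' @param norm_cov Numeric vector of normalized coverages (or a
#'   window-coverage data.frame with a `norm_cov` column).
#' @param model A [robust_normal()] object.
#' @return Factor with levels LOW, NORMAL, HIGH.
#' @export
classify_coverage <- function(norm_cov, model) {
  stopifnot(inherits(model, "robust_normal"))
  if (is.data.frame(norm_cov)) norm_cov <- norm_cov$norm_cov
  lab <- ifelse(norm_cov > model$high_cut, "HIGH",
                ifelse(norm_cov < model$low_cut, "LOW", "NORMAL"))
  factor(lab, levels = c("LOW", "NORMAL", "HIGH"))
}

## ---- multimappers ----------------------------------------------------------

#' Flag windows dominated by multimapped reads
#'
#' A read is treated as multimapped when its mapping quality is 0 (the
#' aligner convention for reads with several equally good placements);
#' alternatively any predicate can be supplied. Windows in which more than
#' `threshold_pct` percent of overlapping reads are multimapped are flagged
#' and merged; windows with no reads are not flagged.
#'
#' @param reads Alignment table from [read_alignments()] (the original,
#'   unfiltered file).
#' @param windows `GRanges` of non-overlapping windows.
#' @param threshold_pct Flag windows with multimapper percentage strictly
#'   above this (default 50).
#' @param is_multimapped Logical vector parallel to `reads`, or NULL for
#'   the `mapq == 0` convention.
#' @return List with `table` (per-window `raw_read_count`, `mm_read_count`,
#'   `pct`) and `flagged` (merged `GRanges` of flagged windows).
#' @export
multimap_windows <- function(reads, windows, threshold_pct = 50,
                             is_multimapped = NULL) {
  if (is.null(is_multimapped)) is_multimapped <- reads$mapq == 0L
  rg <- reads_to_granges(reads)
  raw <- countOverlaps(windows, rg, ignore.strand = TRUE)
  mmc <- countOverlaps(windows, rg[is_multimapped], ignore.strand = TRUE)
  pct <- ifelse(raw == 0, 0, 100 * mmc / raw)
  tab <- data.frame(chrom = as.character(seqnames(windows)),
                    start = start(windows) - 1L, end = end(windows),
                    raw_read_count = raw, mm_read_count = mmc, pct = pct)
  list(table = tab, flagged = merge_intervals(windows[pct > threshold_pct]))
}

#' Attribute low-coverage territory to multimapper dominance
#'
#' Reports which fraction of multimapper-dominated regions fall inside the
#' LC track, which fraction of LC regions contain multimapper regions
#' (both by feature count, >= 1 bp overlap), and the median per-window raw
#' read count genome-wide versus inside LC windows that are not
#' multimapper-dominated.
#'
#' @param lc_regions Merged LC `GRanges`.
#' @param mm_regions Merged multimapper-region `GRanges`.
#' @param window_table The `table` component of [multimap_windows()].
#' @return List with `pct_mm_in_lc`, `pct_lc_in_mm`,
#'   `median_reads_all`, `median_reads_lc_not_mm`.
#' @export
lc_attribution <- function(lc_regions, mm_regions, window_table = NULL) {
  pct_mm_in_lc <- if (length(mm_regions) == 0) 0 else
    100 * mean(countOverlaps(mm_regions, lc_regions, ignore.strand = TRUE) > 0)
  pct_lc_in_mm <- if (length(lc_regions) == 0) 0 else
    100 * mean(countOverlaps(lc_regions, mm_regions, ignore.strand = TRUE) > 0)
  med_all <- med_lc <- NA_real_
  if (!is.null(window_table)) {
    wg <- intervals(window_table$chrom, window_table$start, window_table$end)
    med_all <- stats::median(window_table$raw_read_count)
    in_lc <- countOverlaps(wg, lc_regions, ignore.strand = TRUE) > 0
    in_mm <- countOverlaps(wg, mm_regions, ignore.strand = TRUE) > 0
    sel <- in_lc & !in_mm
    med_lc <- if (any(sel)) stats::median(window_table$raw_read_count[sel]) else NA_real_
  }
  list(pct_mm_in_lc = pct_mm_in_lc, pct_lc_in_mm = pct_lc_in_mm,
       median_reads_all = med_all, median_reads_lc_not_mm = med_lc)
}
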