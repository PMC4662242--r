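## Insert-size model, per-window abnormal-read fractions, 2-SD thresholds.

#' Fit the library insert-size model
#'
#' Mean and SD of the absolute template length of properly paired reads
#' (FR orientation, both mates on one chromosome), after discarding
#' template lengths above 10x the median (chimeric/artefact tail).
#' Cutoffs are `mean +/- 2*sd`: inserts strictly below `small_cut` are
#' abnormally small, strictly above `large_cut` abnormally large.
#'
#' @param reads Alignment table from [read_alignments()].
#' @param min_pairs Minimum usable pairs (default 1000).
#' @return Object of class `insert_model` with `mean`, `sd`, `small_cut`,
#'   `large_cut`, `n_pairs`.
#' @export
fit_insert_model <- function(reads, min_pairs = 1000) {
  tl <- reads$isize[reads$proper & reads$isize > 0]
  tl <- tl[tl <= 10 * stats::median(tl)]
  if (length(tl) < min_pairs)
    stop("fit_insert_model: only ", length(tl), " usable pairs (need >= ", min_pairs, ")")
  m <- mean(tl); s <- stats::sd(tl)
  if (!is.finite(s) || s == 0)
    stop("fit_insert_model: degenerate insert-size distribution (sd = 0)")
  insert_model(m, s, n_pairs = length(tl))
}

#' Construct an insert-size model from known moments
#' @param mean,sd Insert-size mean and SD in bp (`sd > 0`).
#' @param n_pairs Number of pairs behind the estimate (bookkeeping only).
#' @return An `insert_model` object (see [fit_insert_model()]).
#' @export
insert_model <- function(mean, sd, n_pairs = NA_integer_) {
  if (!is.finite(sd) || sd <= 0) stop("insert_model: sd must be > 0")
  structure(list(mean = mean, sd = sd,
                 small_cut = mean - 2 * sd, large_cut = mean + 2 * sd,
                 n_pairs = n_pairs),
            class = "insert_model")
}

#' @export
print.insert_model <- function(x, ...) {
  cat(sprintf("insert_model: mean %.1f bp, sd %.1f bp -> abnormal below %.1f / above %.1f\n",
              x$mean, x$sd, x$small_cut, x$large_cut))
  invisible(x)
}

## ---- per-window fractions --------------------------------------------------

window_fraction_table <- function(reads, windows, in_subset) {
  rg <- reads_to_granges(reads)
  total <- countOverlaps(windows, rg, ignore.strand = TRUE)
  subs <- countOverlaps(windows, rg[in_subset], ignore.strand = TRUE)
  data.frame(chrom = as.character(seqnames(windows)),
             start = start(windows) - 1L, end = end(windows),
             subset_count = subs, total_count = total,
             pct = ifelse(total == 0, 0, 100 * subs / total))
}

#' Per-window percentages of abnormally small/large-insert reads
#'
#' For each (typically overlapping) window, the percentage of overlapping
#' reads whose absolute template length is strictly below the model's
#' small cutoff, and strictly above its large cutoff. A read is "in" a
#' window if its own aligned span overlaps it; reads with no recorded
#' template length (unmapped mate) count in the denominator only. The two
#' classifications are mutually exclusive per read.
#'
#' @param reads Alignment table (the original, unfiltered file).
#' @param model An [insert_model()].
#' @param windows `GRanges` of windows (width 1000, step 800 in the
#'   standard pipeline).
#' @return List of two window-fraction `data.frame`s, `small` and `large`,
#'   each with `subset_count`, `total_count`, `pct`.
#' @export
abnormal_insert_fractions <- function(reads, model, windows) {
  stopifnot(inherits(model, "insert_model"))
  atl <- abs(reads$isize)
  small <- atl > 0 & atl < model$small_cut
  large <- atl > model$large_cut
  list(small = window_fraction_table(reads, windows, small),
       large = window_fraction_table(reads, windows, large))
}

#' Per-window percentage of properly paired reads
#'
#' @param reads Alignment table (the original, unfiltered file); the
#'   proper-pair flag (0x2) must be present.
#' @param windows `GRanges` of windows.
#' @return A window-fraction `data.frame` (`pct` = percent of overlapping
#'   reads flagged properly paired; empty windows report 0 and are
#'   excluded from threshold fitting).
#' @export
proper_pair_fractions <- function(reads, windows) {
  window_fraction_table(reads, windows, reads$proper)
}

## ---- thresholds ------------------------------------------------------------

#' Construct a window-fraction threshold from known moments
#'
#' @param mean_pct,sd_pct Mean and SD of the per-window percentages.
#' @param direction `"above"` flags windows strictly above
#'   `mean + k*sd` (small/large-insert tracks); `"below"` flags windows
#'   strictly below `mean - k*sd` (proper-pairing track).
#' @param k SD multiplier (default 2).
#' @return Object of class `fraction_threshold` with `mean_pct`, `sd_pct`,
#'   `direction`, `k`, `cutoff`.
#' @examples
#' fraction_threshold(4.22, 2.625, "above")$cutoff   # 9.47
#' fraction_threshold(92.5, 10.955, "below")$cutoff  # 70.59
#' @export
fraction_threshold <- function(mean_pct, sd_pct, direction = c("above", "below"),
                               k = 2) {
  direction <- match.arg(direction)
  cutoff <- if (direction == "above") mean_pct + k * sd_pct else mean_pct - k * sd_pct
  structure(list(mean_pct = mean_pct, sd_pct = sd_pct, direction = direction,
                 k = k, cutoff = cutoff),
            class = "fraction_threshold")
}

#' @export
print.fraction_threshold <- function(x, ...) {
  cat(sprintf("fraction_threshold: mean %.3f%%, sd %.3f%% -> abnormal %s %.3f%%\n",
              x$mean_pct, x$sd_pct, x$direction, x$cutoff))
  invisible(x)
}

#' Fit a 2-SD window-fraction threshold
#'
#' Plain (non-robust) mean and SD of the per-window percentages over
#' windows with at least one read; empty windows are excluded so
#' unsequenced territory does not deflate the mean.
#'
#' @param fractions A window-fraction `data.frame` (see
#'   [abnormal_insert_fractions()], [proper_pair_fractions()]).
#' @param direction `"above"` or `"below"` (which tail is abnormal).
#' @param k SD multiplier (default 2).
#' @param min_windows Minimum non-empty windows (default 100).
#' @return A [fraction_threshold()].
#' @export
fit_fraction_threshold <- function(fractions, direction = c("above", "below"),
                                   k = 2, min_windows = 100) {
  direction <- match.arg(direction)
  p <- fractions$pct[fractions$total_count > 0]
  if (length(p) < min_windows)
    stop("fit_fraction_threshold: only ", length(p), " non-empty windows")
  fraction_threshold(mean(p), stats::sd(p), direction, k)
}

#' Flag and merge windows beyond a fraction threshold
#'
#' Windows whose percentage lies strictly beyond the cutoff (above or below
#' per the threshold's direction) are flagged; overlapping/bookended
#' flagged windows are merged into regions. Empty windows are never
#' flagged.
#'
#' @param fractions A window-fraction `data.frame`.
#' @param threshold A [fraction_threshold()].
#' @return Merged `GRanges` of flagged regions.
#' @export
flag_windows <- function(fractions, threshold) {
  stopifnot(inherits(threshold, "fraction_threshold"))
  hit <- if (threshold$direction == "above")
    fractions$pct > threshold$cutoff else fractions$pct < threshold$cutoff
  hit <- hit & fractions$total_count > 0
  merge_intervals(intervals(fractions$chrom[hit], fractions$start[hit],
                            fractions$end[hit]))
}
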