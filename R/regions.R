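## LQ / LC / LQLC region assembly and Table-style summary & overlap reports.

LQ_EVIDENCE <- c("HIGH_COV", "SMALL_INSERT", "LARGE_INSERT", "IMPROPER_PAIR",
                 "HOM_VARIANT")

#' Build the low-quality (LQ) region track
#'
#' LQ regions carry the strongest misassembly evidence: the merged union of
#' high-coverage windows, high small-insert-fraction windows, high
#' large-insert-fraction windows, low proper-pairing windows, and the
#' flanked homozygous-variant regions. Low coverage and multimapper
#' dominance never contribute to LQ (they form the separate LC track).
#'
#' @param high_cov,small_insert,large_insert,improper_pair,hom_variant
#'   Merged evidence `GRanges` (any may be empty).
#' @return Merged `GRanges` with a `reasons` metadata column giving the
#'   comma-joined evidence classes overlapping each region.
#' @export
build_lq <- function(high_cov = GRanges(), small_insert = GRanges(),
                     large_insert = GRanges(), improper_pair = GRanges(),
                     hom_variant = GRanges()) {
  tracks <- list(HIGH_COV = high_cov, SMALL_INSERT = small_insert,
                 LARGE_INSERT = large_insert, IMPROPER_PAIR = improper_pair,
                 HOM_VARIANT = hom_variant)
  all <- suppressWarnings(do.call(c, unname(lapply(tracks, function(g) {
    GRanges(seqnames(g), IRanges::ranges(g))
  }))))
  lq <- merge_intervals(all)
  if (length(lq) > 0) {
    reasons <- vapply(seq_along(lq), function(i) {
      hit <- vapply(tracks, function(g)
        length(g) > 0 && countOverlaps(lq[i], g, ignore.strand = TRUE) > 0, NA)
      paste(names(tracks)[hit], collapse = ",")
    }, "")
    mcols(lq)$reasons <- reasons
  }
  lq
}

#' Build the low-coverage (LC) track
#'
#' @param low_cov `GRanges` of low-coverage windows.
#' @return Merged `GRanges`.
#' @export
build_lc <- function(low_cov) merge_intervals(low_cov)

#' Build the combined LQLC track (merged union of LQ and LC)
#'
#' @param lq,lc Merged `GRanges`.
#' @return Merged `GRanges`; its base total never exceeds the sum of the
#'   two inputs' base totals.
#' @export
build_lqlc <- function(lq, lc) {
  merge_intervals(suppressWarnings(c(GRanges(seqnames(lq), IRanges::ranges(lq)),
                                     GRanges(seqnames(lc), IRanges::ranges(lc)))))
}

#' Summarize a region track against the genome
#'
#' Feature count, mean feature size, and percentage of the genome covered
#' (genome size taken from the layout minus any excluded chromosomes,
#' e.g. a Y chromosome when the sequenced individual is female).
#'
#' @param regions Merged `GRanges`.
#' @param layout A [genome_layout()].
#' @param excluded_chroms Chromosome names excluded from the denominator
#'   (and from the regions).
#' @return List with `n_features`, `mean_size` (0 when empty),
#'   `total_bases`, `pct_genome`.
#' @export
summarize_regions <- function(regions, layout, excluded_chroms = character(0)) {
  keep_chr <- setdiff(names(layout), excluded_chroms)
  gsize <- sum(as.numeric(layout[keep_chr]))
  regions <- regions[as.character(seqnames(regions)) %in% keep_chr]
  n <- length(regions)
  tb <- total_bases(regions)
  list(n_features = n,
       mean_size = if (n == 0) 0 else tb / n,
       total_bases = tb,
       pct_genome = 100 * tb / gsize)
}

#' Percentage helper used by all overlap reports
#'
#' @param count Features or bases overlapping.
#' @param total Total features or bases.
#' @return `100 * count / total` (0 when `total` is 0), unrounded.
#' @export
overlap_pct <- function(count, total) ifelse(total == 0, 0, 100 * count / total)

#' Overlap report of an annotation set against LQ / LC / LQLC
#'
#' In `feature_count` mode (point variants, CNVR intervals) an annotation
#' feature is "in" a track when it overlaps it by at least 1 bp; counts and
#' percentages of features are reported. In `base_count` mode (coding
#' region, gene models) the overlapping base totals are reported instead.
#'
#' @param annotation `GRanges` of annotation features.
#' @param lq,lc,lqlc Merged region tracks.
#' @param mode `"feature_count"` or `"base_count"`.
#' @param name Annotation display name.
#' @return List of class `overlap_report`: `name`, `mode`, `total`, and for
#'   each track `in_<track>` and `pct_<track>` (unrounded).
#' @export
overlap_report <- function(annotation, lq, lc, lqlc,
                           mode = c("feature_count", "base_count"),
                           name = "annotation") {
  mode <- match.arg(mode)
  if (mode == "feature_count") {
    total <- length(annotation)
    f <- function(track) sum(countOverlaps(annotation, track, ignore.strand = TRUE) > 0)
  } else {
    am <- merge_intervals(annotation)
    total <- total_bases(am)
    f <- function(track) intersect_sets(am, track)$overlap_bases
  }
  in_lq <- f(lq); in_lc <- f(lc); in_lqlc <- f(lqlc)
  structure(list(name = name, mode = mode, total = total,
                 in_lq = in_lq, pct_lq = overlap_pct(in_lq, total),
                 in_lc = in_lc, pct_lc = overlap_pct(in_lc, total),
                 in_lqlc = in_lqlc, pct_lqlc = overlap_pct(in_lqlc, total)),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  unit <- if (x$mode == "feature_count") "features" else "bases"
  cat(sprintf("%s: %s %s total; LQ %s (%.2f%%), LC %s (%.2f%%), LQLC %s (%.2f%%)\n",
              x$name, format(x$total, big.mark = ","), unit,
              format(x$in_lq, big.mark = ","), x$pct_lq,
              format(x$in_lc, big.mark = ","), x$pct_lc,
              format(x$in_lqlc, big.mark = ","), x$pct_lqlc))
  invisible(x)
}
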