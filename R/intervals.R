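#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width reduce coverage
#'   findOverlaps countOverlaps pintersect
#' @importFrom IRanges IRanges Views viewApply subsetByOverlaps
#' @importFrom S4Vectors queryHits subjectHits mcols mcols<-
NULL

## ---- genome layout ---------------------------------------------------------

#' Define a genome layout (ordered chromosome sizes)
#'
#' A genome layout is the ordered set of sequence names and lengths that all
#' interval operations are anchored to: windows are tiled over it, per-base
#' depth tracks allocate one value per base of it, and "percentage of genome"
#' summaries use its total size as denominator.
#'
#' @param lengths Named numeric vector of chromosome lengths in bases
#'   (names are chromosome names), or a `data.frame` with columns
#'   `chrom` and `length`.
#' @return A named integer-valued numeric vector with class `genome_layout`.
#' @examples
#' genome_layout(c(chr1 = 5e5, chr2 = 2e5))
#' @export
genome_layout <- function(lengths) {
  if (is.data.frame(lengths)) {
    stopifnot(all(c("chrom", "length") %in% names(lengths)))
    lengths <- stats::setNames(as.numeric(lengths$length), as.character(lengths$chrom))
  }
  if (is.null(names(lengths)) || any(!nzchar(names(lengths))))
    stop("genome_layout: every chromosome needs a non-empty name")
  if (anyDuplicated(names(lengths)))
    stop("genome_layout: duplicated chromosome names")
  if (any(!is.finite(lengths)) || any(lengths <= 0) || any(lengths != floor(lengths)))
    stop("genome_layout: lengths must be positive integers")
  structure(lengths, class = "genome_layout")
}

#' Total genome size of a layout
#' @param layout A [genome_layout()].
#' @return Total number of bases.
#' @export
layout_size <- function(layout) sum(unclass(layout))

#' Read a two-column chromosome-sizes file
#' @param path Path to a tab-separated `chrom<TAB>length` file.
#' @return A [genome_layout()].
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "numeric"))
  genome_layout(stats::setNames(df$length, df$chrom))
}

#' Write a chromosome-sizes file
#' @param layout A [genome_layout()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(layout, path) {
  utils::write.table(data.frame(names(layout), as.numeric(layout)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @export
print.genome_layout <- function(x, ...) {
  cat("genome_layout:", length(x), "sequence(s),",
      format(layout_size(x), big.mark = ","), "bases\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

as_seqinfo <- function(layout) {
  GenomeInfoDb::Seqinfo(seqnames = names(layout), seqlengths = as.numeric(layout))
}

## ---- construction / validation --------------------------------------------

#' Build a genomic interval set
#'
#' Interval sets are held as [GenomicRanges::GRanges] objects. Externally
#' (BED files, function arguments named `start`/`end`) coordinates are
#' 0-based half-open; internally GRanges' 1-based closed convention is used.
#' This constructor takes 0-based half-open coordinates.
#'
#' @param chrom Character vector of chromosome names.
#' @param start 0-based inclusive start offsets.
#' @param end Exclusive end offsets; must satisfy `start < end`.
#' @return A `GRanges` object.
#' @export
intervals <- function(chrom, start, end) {
  if (length(chrom) == 0) return(GRanges())
  if (any(start < 0) || any(start >= end))
    stop("intervals: need 0 <= start < end")
  GRanges(chrom, IRanges(start = start + 1, end = end))
}

#' Total bases in an interval set (sum of interval widths)
#' @param gr A `GRanges`.
#' @return Number of bases, counting overlapping bases multiply; apply
#'   [merge_intervals()] first for a union size.
#' @export
total_bases <- function(gr) sum(as.numeric(width(gr)))

## ---- windows ---------------------------------------------------------------

#' Tile a genome layout with (possibly overlapping) fixed-width windows
#'
#' Windows advance from offset 0 of each chromosome by `step`; the final
#' window of a chromosome is truncated at the chromosome end. With
#' `step == width` this partitions each chromosome exactly; with
#' `step < width` consecutive windows overlap by `width - step` bases.
#' Every base is covered by at least one window.
#'
#' @param layout A [genome_layout()].
#' @param width Window width in bases.
#' @param step Distance between successive window starts; `0 < step <= width`
#'   (a step larger than the width would leave uncovered bases and is
#'   rejected).
#' @return A `GRanges` of windows, ordered by chromosome then start.
#' @export
make_windows <- function(layout, width, step = width) {
  stopifnot(inherits(layout, "genome_layout"))
  if (width <= 0) stop("make_windows: width must be > 0")
  if (step <= 0 || step > width)
    stop("make_windows: need 0 < step <= width (step > width leaves gaps)")
  pieces <- lapply(names(layout), function(chr) {
    len <- as.numeric(layout[[chr]])
    starts <- seq(0, max(0, len - 1), by = step)
    starts <- starts[starts < len]
    ends <- pmin(starts + width, len)
    # a trailing window fully contained in its predecessor adds nothing
    keep <- c(TRUE, ends[-1] > ends[-length(ends)])[seq_along(starts)]
    data.frame(chrom = chr, start = starts[keep], end = ends[keep])
  })
  df <- do.call(rbind, pieces)
  ans <- GRanges(df$chrom, IRanges(start = df$start + 1, end = df$end))
  GenomeInfoDb::seqlevels(ans) <- names(layout)
  ans
}

## ---- merge / intersect -----------------------------------------------------

#' Merge an interval set into its minimal disjoint union
#'
#' Overlapping and bookended (touching) intervals are fused, matching the
#' default behaviour of `bedtools merge` with distance 0. Idempotent.
#'
#' @param gr A `GRanges`.
#' @return A sorted `GRanges` of non-overlapping, non-adjacent intervals
#'   covering exactly the union of input bases.
#' @export
merge_intervals <- function(gr) {
  if (length(gr) == 0) return(GRanges())
  reduce(GenomicRanges::sort(gr), min.gapwidth = 1L)
}

#' Intersect two interval sets
#'
#' Reports both the feature-count view (how many intervals of `a` touch `b`
#' at all, used for point-variant and CNVR style annotations) and the
#' base-count view (how many bases of the union of `a` fall inside the union
#' of `b`, used for coding-region style annotations).
#'
#' @param a,b `GRanges` objects.
#' @return A list with `features` (the subset of `a` with >= 1 bp overlap
#'   with `b`), `n_features`, and `overlap_bases` (bases of
#'   `merge(a)` covered by `merge(b)`).
#' @export
intersect_sets <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    return(list(features = a[integer(0)], n_features = 0L, overlap_bases = 0))
  }
  hit <- countOverlaps(a, b, ignore.strand = TRUE) > 0
  am <- merge_intervals(a)
  bm <- merge_intervals(b)
  ov <- suppressWarnings(GenomicRanges::intersect(am, bm, ignore.strand = TRUE))
  list(features = a[hit], n_features = sum(hit), overlap_bases = total_bases(ov))
}

#' Drop windows that touch assembly gaps
#'
#' Any window with at least 1 bp of overlap with a gap interval is removed
#' entirely (any-overlap semantics); windows merely bookended against a gap
#' are kept.
#'
#' @param windows,gaps `GRanges` objects.
#' @return The subset of `windows` overlapping no gap.
#' @export
remove_gap_windows <- function(windows, gaps) {
  if (length(gaps) == 0 || length(windows) == 0) return(windows)
  windows[countOverlaps(windows, gaps, ignore.strand = TRUE) == 0]
}

## ---- depth -----------------------------------------------------------------

#' Per-base fragment depth across a genome layout
#'
#' `depth[x]` is the number of fragment intervals containing base `x`, for
#' every base of the layout (zero where nothing aligns). Fragments falling
#' outside the layout are rejected with their identity reported.
#'
#' @param fragments `GRanges` of fragment outer spans.
#' @param layout A [genome_layout()].
#' @return An [IRanges::RleList] with one run-length-encoded integer vector
#'   per chromosome, each of exactly the chromosome's length.
#' @export
fragment_depth <- function(fragments, layout) {
  stopifnot(inherits(layout, "genome_layout"))
  if (length(fragments) > 0) {
    chr <- as.character(seqnames(fragments))
    bad <- !(chr %in% names(layout)) |
      start(fragments) < 1 | end(fragments) > as.numeric(layout[chr])
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("fragment_depth: fragment %d (%s:%d-%d) outside layout",
                   i, chr[i], start(fragments)[i] - 1L, end(fragments)[i]))
    }
  }
  gr <- GRanges(seqnames = if (length(fragments)) seqnames(fragments) else character(0),
                ranges = if (length(fragments)) IRanges::ranges(fragments) else IRanges(),
                seqinfo = as_seqinfo(layout))
  coverage(gr)
}

## ---- BED I/O ---------------------------------------------------------------

#' Read a BED3+ file
#'
#' Parses a 3+ column BED file (0-based half-open). Extra columns are kept
#' as metadata columns `name`, `score`, ... in order. Malformed records
#' (non-integer coordinates, `start >= end`) raise an error naming the line.
#'
#' @param path Path to a BED file.
#' @return A `GRanges`; extra BED columns appear in `mcols()`.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0) return(GRanges())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3))
    stop(sprintf("read_bed: line %d has fewer than 3 columns", lineno[which(ncol < 3)[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  s <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  e <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- !is.finite(s) | !is.finite(e) | s != floor(s) | e != floor(e)
  if (any(bad))
    stop(sprintf("read_bed: line %d: non-integer coordinates", lineno[which(bad)[1]]))
  bad <- s < 0 | s >= e
  if (any(bad))
    stop(sprintf("read_bed: line %d: requires 0 <= start < end", lineno[which(bad)[1]]))
  gr <- GRanges(chrom, IRanges(start = s + 1, end = e))
  extra <- max(ncol) - 3L
  if (extra > 0) {
    extra_names <- c("name", "score", "strand")[seq_len(min(extra, 3L))]
    if (extra > 3) extra_names <- c(extra_names, paste0("V", 7:(3 + extra)))
    for (j in seq_len(extra)) {
      mcols(gr)[[extra_names[j]]] <-
        vapply(fields, function(f) if (length(f) >= j + 3) f[[j + 3]] else NA_character_, "")
    }
  }
  gr
}

#' Write an interval set as BED
#'
#' Writes canonical BED3, 0-based half-open, or BED4 when `name` is given.
#' Re-reading a written file reproduces the intervals exactly.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @param name Optional character vector (length 1 or `length(gr)`) written
#'   as a fourth column.
#' @return `path`, invisibly.
#' @export
write_bed <- function(gr, path, name = NULL) {
  df <- data.frame(chrom = as.character(seqnames(gr)),
                   start = format(start(gr) - 1L, scientific = FALSE, trim = TRUE),
                   end = format(end(gr), scientific = FALSE, trim = TRUE))
  if (!is.null(name)) df$name <- rep_len(as.character(name), nrow(df))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
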