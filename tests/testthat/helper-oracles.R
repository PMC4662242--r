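# Per-base brute-force oracles and small fixture builders shared by the
# suite. Oracles operate on plain logical/integer vectors, independent of
# the GRanges-based implementation they check.

# logical per-base mask (length len) covered by a set of 0-based intervals
mask_from_intervals <- function(start, end, len) {
  m <- logical(len)
  for (i in seq_along(start)) m[(start[i] + 1):end[i]] <- TRUE
  m
}

# 0-based half-open runs of TRUE in a mask (the brute-force "merge")
runs_from_mask <- function(m) {
  r <- rle(m)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# integer per-base depth from 0-based fragments (the brute-force genomecov)
depth_from_intervals <- function(start, end, len) {
  d <- integer(len)
  for (i in seq_along(start)) {
    idx <- (start[i] + 1):end[i]
    d[idx] <- d[idx] + 1L
  }
  d
}

random_interval_set <- function(n, len, max_width = 500) {
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(w, function(wi) sample.int(len - wi + 1, 1) - 1L, 0L)
  data.frame(start = s, end = s + w)
}

gr1 <- function(start, end, chrom = "chr1") intervals(rep(chrom, length(start)), start, end)

# minimal alignment table (the read_alignments() contract) for unit tests
fake_reads <- function(start, end, chrom = "chr1", mapq = 60L, isize = 0L,
                       proper = TRUE, qname = NULL, flag = NULL) {
  n <- length(start)
  data.table::data.table(
    qname = qname %||% sprintf("r%04d", seq_len(n)),
    flag = flag %||% rep(99L, n),
    chrom = rep_len(chrom, n),
    start = as.integer(start), end = as.integer(end),
    mapq = as.integer(rep_len(mapq, n)),
    isize = as.integer(rep_len(isize, n)),
    proper = rep_len(proper, n),
    mate_unmapped = rep_len(FALSE, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
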