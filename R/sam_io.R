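#' @importFrom Rsamtools asBam scanBam ScanBamParam scanBamFlag BamFile
#'   PileupParam pileup sortBam indexBam
#' @importFrom data.table data.table setkey := .N setorder as.data.table
NULL

utils::globalVariables(c(
  ".", "qname", "flag", "mapq", "isize", "chrom", "start", "end",
  "proper", "mm", "n_mates", "min_mapq_pair", "all_proper", "frag_start",
  "frag_end", "pos"
))

#' Open an alignment file (SAM or BAM) as an indexed BAM
#'
#' Plain-text SAM input is converted to a coordinate-sorted, indexed BAM in
#' a scratch directory; BAM input is indexed if needed. All downstream
#' readers work from the returned BAM path.
#'
#' @param path Path to a SAM (`.sam`) or BAM (`.bam`) file with a valid
#'   header. Input must be coordinate-sortable; unsorted SAM is sorted
#'   during conversion.
#' @param dest Optional destination prefix for the converted BAM.
#' @return Path to an indexed BAM file.
#' @export
open_alignments <- function(path, dest = NULL) {
  if (!file.exists(path)) stop("open_alignments: no such file: ", path)
  if (grepl("\\.bam$", path, ignore.case = TRUE)) {
    if (!file.exists(paste0(path, ".bai"))) indexBam(path)
    return(path)
  }
  if (is.null(dest)) dest <- tempfile("asmqc_aln")
  bam <- suppressWarnings(asBam(path, dest, overwrite = TRUE, indexDestination = TRUE))
  bam
}

#' Load per-read alignment records into a table
#'
#' Reads the fields the window metrics need: name, flag, chromosome,
#' 0-based start, end (reference span from the CIGAR), mapping quality and
#' template length. Unmapped records are dropped.
#'
#' @param bam Path to an indexed BAM (see [open_alignments()]).
#' @return A `data.table` with columns `qname`, `flag`, `chrom`, `start`
#'   (0-based), `end` (exclusive), `mapq`, `isize`, `proper` (flag 0x2),
#'   `mate_unmapped` (flag 0x8).
#' @export
read_alignments <- function(bam) {
  p <- ScanBamParam(what = c("qname", "flag", "rname", "pos", "mapq", "cigar", "isize"),
                    flag = scanBamFlag(isUnmappedQuery = FALSE))
  x <- scanBam(bam, param = p)[[1]]
  rw <- GenomicAlignments::cigarWidthAlongReferenceSpace(x$cigar)
  dt <- data.table(
    qname = x$qname,
    flag = x$flag,
    chrom = as.character(x$rname),
    start = x$pos - 1L,
    end = x$pos - 1L + rw,
    mapq = as.integer(x$mapq),
    isize = ifelse(is.na(x$isize), 0L, x$isize),
    proper = bitwAnd(x$flag, 2L) != 0L,
    mate_unmapped = bitwAnd(x$flag, 8L) != 0L
  )
  dt
}

reads_to_granges <- function(reads) {
  GRanges(reads$chrom, IRanges(start = reads$start + 1L, end = reads$end))
}

#' Extract whole-fragment spans from paired alignments
#'
#' One interval per retained read pair, spanning the leftmost mate start to
#' the rightmost mate end (the sequenced fragment's outer footprint). A pair
#' is retained only if both mates are mapped to the same chromosome with
#' mapping quality at least `min_mapq` and (when `require_proper`) both
#' carry the proper-pair flag. Orphaned reads surviving alone are skipped
#' and counted.
#'
#' @param reads Alignment table from [read_alignments()].
#' @param min_mapq Minimum mapping quality for both mates (default 2).
#' @param require_proper Drop pairs not flagged as properly paired
#'   (default TRUE).
#' @return A `GRanges` of fragment spans, with attribute `n_orphans`
#'   (reads whose mate did not survive filtering).
#' @export
extract_fragments <- function(reads, min_mapq = 2, require_proper = TRUE) {
  r <- reads[mapq >= min_mapq]
  if (require_proper) r <- r[proper == TRUE]
  if (nrow(r) == 0) {
    out <- GRanges()
    attr(out, "n_orphans") <- 0L
    return(out)
  }
  pr <- r[, .(n_mates = .N,
              chrom = chrom[1],
              same_chrom = data.table::uniqueN(chrom) == 1L,
              frag_start = min(start),
              frag_end = max(end)), by = qname]
  ok <- pr$n_mates == 2L & pr$same_chrom
  n_orphans <- sum(pr$n_mates == 1L)
  pr <- pr[ok]
  out <- GRanges(pr$chrom, IRanges(start = pr$frag_start + 1L, end = pr$frag_end))
  out <- GenomicRanges::sort(out)
  attr(out, "n_orphans") <- n_orphans
  out
}

#' Write alignment records as a coordinate-sorted SAM file
#'
#' Minimal SAM writer used by the simulator: takes a table of records
#' already carrying all eleven mandatory fields and writes a valid,
#' coordinate-sorted SAM with `@HD`/`@SQ` headers.
#'
#' @param rec A `data.frame`/`data.table` with columns `qname`, `flag`,
#'   `chrom`, `pos` (1-based), `mapq`, `cigar`, `mchrom`, `mpos`, `tlen`,
#'   `seq`, `qual`.
#' @param layout A [genome_layout()] describing the target assembly.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(rec, layout, path) {
  rec <- as.data.table(rec)
  setorder(rec, chrom, pos, qname)
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(layout), as.integer(layout)))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
                  rec$qname, as.integer(rec$flag), rec$chrom, as.integer(rec$pos),
                  as.integer(rec$mapq), rec$cigar, rec$mchrom, as.integer(rec$mpos),
                  as.integer(rec$tlen), rec$seq, rec$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}
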