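write_test_vcf <- function(rows, samples = "S1") {
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rows), f)
  f
}

test_that("VCF genotypes classify into hom_ref / het / hom_alt", {
  f <- write_test_vcf(c(
    "chr1\t1000\t.\tA\tG\t50\tPASS\t.\tGT\t1/1",
    "chr1\t2000\t.\tC\tT\t50\tPASS\t.\tGT\t0/1",
    "chr1\t3000\t.\tG\tA\t50\tPASS\t.\tGT\t0/0",
    "chr1\t4000\t.\tT\tA,C\t50\tPASS\t.\tGT\t1/2",
    "chr1\t5000\t.\tA\tC\t50\tPASS\t.\tGT\t./."))
  v <- load_variants(f)
  expect_equal(v$gt_class, c("hom_alt", "het", "hom_ref", "het"))
  expect_equal(v$pos, c(999L, 1999L, 2999L, 3999L))  # 0-based
  expect_equal(attr(v, "n_skipped"), 1L)
})

test_that("multi-sample VCF is rejected", {
  f <- write_test_vcf("chr1\t1000\t.\tA\tG\t50\tPASS\t.\tGT\t1/1\t0/1",
                      samples = c("S1", "S2"))
  expect_error(load_variants(f), "single-sample")
})

test_that("homozygous sites expand to clipped, merged +/-100 bp regions", {
  lay <- genome_layout(c(chr1 = 100000))
  s1 <- data.frame(chrom = "chr1", pos = 999L, ref = "A", alt = "G",
                   gt_class = "hom_alt")
  r <- homozygous_regions(s1, lay)
  expect_equal(c(start(r) - 1L, end(r)), c(899L, 1100L))
  expect_equal(width(r), 201L)

  s2 <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G",
                   gt_class = "hom_alt")
  r <- homozygous_regions(s2, lay)
  expect_equal(c(start(r) - 1L, end(r)), c(0L, 111L))

  # two SNVs 150 bp apart merge; an indel footprint widens the region
  s3 <- data.frame(chrom = "chr1", pos = c(1000L, 1150L, 5000L),
                   ref = c("A", "A", "ATTT"), alt = c("G", "G", "A"),
                   gt_class = "hom_alt")
  r <- homozygous_regions(s3, lay)
  expect_equal(length(r), 2L)
  expect_equal(width(r), c(351L, 204L))

  # only hom_alt sites contribute; each site lies in exactly one region
  s4 <- rbind(s3, data.frame(chrom = "chr1", pos = 9000L, ref = "A",
                             alt = "G", gt_class = "het"))
  r <- homozygous_regions(s4, lay)
  expect_equal(length(r), 2L)
  hits <- GenomicRanges::countOverlaps(
    intervals(s3$chrom, s3$pos, s3$pos + 1), r)
  expect_true(all(hits == 1L))
})

test_that("internal caller calls hom_alt only for near-unanimous alternates", {
  set.seed(77)
  genome <- Biostrings::DNAStringSet(c(chr1 = paste(
    sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = "")))
  lay <- genome_layout(c(chr1 = 3000))
  rl <- 100L
  # 30 overlapping proper pairs covering position 1500 (1-based)
  p1 <- as.integer(seq(1320, 1494, by = 6))
  p2 <- p1 + 400L
  seqs1 <- as.character(Biostrings::extractAt(
    genome[["chr1"]], IRanges::IRanges(p1, p1 + rl - 1L)))
  seqs2 <- as.character(Biostrings::extractAt(
    genome[["chr1"]], IRanges::IRanges(p2, p2 + rl - 1L)))
  plant_alt <- function(seqs, starts, at, frac) {
    ref <- substring(as.character(genome[["chr1"]]), at, at)
    alt <- setdiff(c("A", "C", "G", "T"), ref)[1]
    covering <- which(starts <= at & starts + rl - 1L >= at)
    hit <- covering[seq_len(round(length(covering) * frac))]
    for (i in hit) {
      off <- at - starts[i] + 1L
      substring(seqs[i], off, off) <- alt
    }
    seqs
  }
  seqs1 <- plant_alt(seqs1, p1, 1500L, 1.0)   # unanimous alternate
  seqs1 <- plant_alt(seqs1, p1, 1400L, 0.5)   # half the covering reads
  rec <- data.table::data.table(
    qname = rep(sprintf("p%03d", seq_along(p1)), 2),
    flag = c(rep(99L, length(p1)), rep(147L, length(p1))),
    chrom = "chr1", pos = c(p1, p2), mapq = 60L, cigar = "100M",
    mchrom = "=", mpos = c(p2, p1),
    tlen = c(p2 + rl - p1, -(p2 + rl - p1)),
    seq = c(seqs1, seqs2), qual = strrep("I", rl))
  f <- tempfile(fileext = ".sam")
  write_sam(rec, lay, f)
  sites <- call_homozygous_sites(open_alignments(f), genome)
  hom <- sites[sites$gt_class == "hom_alt", ]
  expect_equal(hom$pos, 1499L)                  # 0-based
  expect_gte(hom$alt_fraction, 0.9)
  het <- sites[sites$gt_class == "het", ]
  expect_true(1399L %in% het$pos)
  expect_false(1399L %in% hom$pos)
})
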