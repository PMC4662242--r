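## Homozygous non-reference variants and their +/- 100 bp low-quality flanks.
##
## When an individual's reads are mapped back to an assembly built from that
## same individual, a homozygous non-reference call means every read
## disagrees with the assembly base - evidence of a consensus error or a
## collapsed duplication, not of biology.

#' Load variant sites from a single-sample VCF
#'
#' Parses sites and classifies the sample genotype: two identical
#' non-reference alleles are `hom_alt`, two reference alleles `hom_ref`,
#' anything mixed (including two different alternates, e.g. `1/2`) `het`.
#' Sites with a missing genotype are skipped and counted.
#'
#' @param path Path to a VCF (v4.x) with exactly one sample.
#' @return A `data.frame` with `chrom`, `pos` (0-based), `ref`, `alt`
#'   (comma-joined), `gt_class`, `depth` (NA if no DP), and attribute
#'   `n_skipped`.
#' @export
load_variants <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  if (ncol(vcf) != 1)
    stop("load_variants: expected a single-sample VCF, found ", ncol(vcf), " samples")
  gt <- as.character(VariantAnnotation::geno(vcf)$GT[, 1])
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- vapply(as.list(VariantAnnotation::alt(vcf)),
                function(a) paste(as.character(a), collapse = ","), "")
  dp <- rep(NA_integer_, length(gt))
  if ("DP" %in% rownames(VariantAnnotation::geno(VariantAnnotation::header(vcf))))
    dp <- as.integer(VariantAnnotation::geno(vcf)$DP[, 1])
  alleles <- strsplit(gt, "[/|]")
  classify <- function(a) {
    if (length(a) == 0 || any(a == "." | !nzchar(a))) return(NA_character_)
    if (all(a == "0")) return("hom_ref")
    if (length(unique(a)) == 1) return("hom_alt")
    "het"
  }
  cls <- vapply(alleles, classify, "")
  keep <- !is.na(cls)
  out <- data.frame(chrom = as.character(seqnames(rr))[keep],
                    pos = start(rr)[keep] - 1L,
                    ref = as.character(VariantAnnotation::ref(vcf))[keep],
                    alt = alt[keep],
                    gt_class = cls[keep],
                    depth = dp[keep])
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Call homozygous non-reference sites directly from alignments
#'
#' A minimal consensus-style caller used by the synthetic pipeline: for
#' each covered position, counts read bases with base quality at least
#' `min_baseq` (from reads with mapping quality at least `min_mapq`), and
#' calls the site homozygous-alternate when depth is at least `min_depth`
#' and the most frequent non-reference base carries at least
#' `min_alt_fraction` of the counted bases. Sites with an alternate
#' fraction between 0.2 and the homozygous floor are reported `het`.
#'
#' @param bam Indexed BAM path (see [open_alignments()]).
#' @param genome Assembly `DNAStringSet` or FASTA path.
#' @param min_depth Minimum counted depth (default 8).
#' @param min_alt_fraction Minimum alternate-base fraction for a homozygous
#'   call (default 0.9).
#' @param min_baseq Minimum base quality (default 13).
#' @param min_mapq Minimum mapping quality (default 2).
#' @return A `data.frame` with `chrom`, `pos` (0-based), `ref`, `alt`,
#'   `gt_class`, `depth`, `alt_fraction`.
#' @export
call_homozygous_sites <- function(bam, genome, min_depth = 8,
                                  min_alt_fraction = 0.9, min_baseq = 13,
                                  min_mapq = 2) {
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  pp <- PileupParam(max_depth = 100000L, min_base_quality = as.integer(min_baseq),
                    min_mapq = as.integer(min_mapq), min_nucleotide_depth = 1L,
                    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
                    include_deletions = FALSE, include_insertions = FALSE)
  pu <- pileup(bam, pileupParam = pp)
  if (nrow(pu) == 0) {
    return(data.frame(chrom = character(0), pos = integer(0), ref = character(0),
                      alt = character(0), gt_class = character(0),
                      depth = integer(0), alt_fraction = numeric(0)))
  }
  pu <- as.data.table(pu)
  pu[, chrom := as.character(seqnames)]
  wide <- data.table::dcast(pu, chrom + pos ~ nucleotide,
                            value.var = "count", fun.aggregate = sum, fill = 0L)
  bases <- intersect(c("A", "C", "G", "T"), names(wide))
  cnt <- as.matrix(wide[, bases, with = FALSE])
  depth <- rowSums(cnt)
  refbase <- character(nrow(wide))
  for (chr in unique(wide$chrom)) {
    i <- which(wide$chrom == chr)
    refbase[i] <- as.character(
      Biostrings::extractAt(genome[[chr]], IRanges(wide$pos[i], wide$pos[i])))
  }
  alt_cnt <- cnt
  ref_idx <- match(refbase, bases)
  ok_ref <- !is.na(ref_idx)
  alt_cnt[cbind(seq_len(nrow(cnt))[ok_ref], ref_idx[ok_ref])] <- 0L
  best_alt <- max.col(alt_cnt, ties.method = "first")
  alt_n <- alt_cnt[cbind(seq_len(nrow(cnt)), best_alt)]
  alt_frac <- ifelse(depth == 0, 0, alt_n / depth)
  cls <- ifelse(depth >= min_depth & alt_frac >= min_alt_fraction, "hom_alt",
                ifelse(depth >= min_depth & alt_frac >= 0.2, "het", "hom_ref"))
  sel <- cls != "hom_ref"
  data.frame(chrom = wide$chrom[sel], pos = wide$pos[sel] - 1L,
             ref = refbase[sel], alt = bases[best_alt[sel]],
             gt_class = cls[sel], depth = as.integer(depth[sel]),
             alt_fraction = alt_frac[sel])
}

#' Expand homozygous variant sites into merged low-quality regions
#'
#' Each homozygous non-reference site is expanded to cover 100 bases before
#' through 100 bases after its reference footprint (201 bp for a SNV, more
#' for indels with a longer reference allele), clipped at chromosome
#' bounds, and the expansions are merged.
#'
#' @param sites Variant `data.frame` from [load_variants()] or
#'   [call_homozygous_sites()]; only `gt_class == "hom_alt"` rows are used.
#' @param layout A [genome_layout()] for bound clipping.
#' @param flank Flank size in bases (default 100).
#' @return Merged `GRanges` of low-quality regions.
#' @export
homozygous_regions <- function(sites, layout, flank = 100) {
  s <- sites[sites$gt_class == "hom_alt", , drop = FALSE]
  if (nrow(s) == 0) return(GRanges())
  ref_len <- nchar(s$ref)
  st <- pmax(0, s$pos - flank)
  en <- pmin(as.numeric(layout[s$chrom]), s$pos + ref_len + flank)
  merge_intervals(intervals(s$chrom, st, en))
}
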