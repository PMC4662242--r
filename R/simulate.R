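## Deterministic simulator: sample genome -> corrupted assembly with planted
## misassemblies -> paired-end alignments projected into assembly
## coordinates -> truth BEDs. Alignment is done by coordinate projection
## (not by running an aligner), which is deterministic and isolates
## detector behaviour from aligner heuristics.

SIM_KINDS <- c("collapsed_duplication", "false_tandem_duplication", "inversion",
               "assembly_deletion", "assembly_insertion", "substitution_error")

#' Simulation configuration
#'
#' @param seed Integer seed fixing all randomness of the simulation.
#' @param chrom_lengths Named vector of sample-genome chromosome lengths.
#' @param depth Target mean per-base fragment coverage.
#' @param insert_mean,insert_sd Fragment (insert) length distribution in bp.
#' @param read_length Read length in bp; `insert_mean` must exceed
#'   `2 * read_length`.
#' @param error_rate Per-base sequencing error rate.
#' @param base_gc Baseline GC fraction of the simulated genome.
#' @param gc_profile Optional `data.frame` (`chrom`, `start`, `end`, `gc`)
#'   of regions with a different target GC fraction (0-based half-open).
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 42, chrom_lengths = c(chr1 = 500000),
                       depth = 40, insert_mean = 427, insert_sd = 80,
                       read_length = 100, error_rate = 0.001,
                       base_gc = 0.5, gc_profile = NULL) {
  stopifnot(depth > 0, insert_mean > 2 * read_length, insert_sd > 0,
            error_rate >= 0, error_rate < 1, base_gc > 0, base_gc < 1)
  genome_layout(chrom_lengths)  # validates lengths
  structure(list(seed = as.integer(seed), chrom_lengths = chrom_lengths,
                 depth = depth, insert_mean = insert_mean,
                 insert_sd = insert_sd, read_length = read_length,
                 error_rate = error_rate, base_gc = base_gc,
                 gc_profile = gc_profile),
            class = "sim_config")
}

#' A planted misassembly
#'
#' Kinds and the alignment signatures they plant (assembly relative to the
#' sample the reads come from):
#' \describe{
#'   \item{collapsed_duplication}{the sample carries two diverged copies of
#'     a segment, the assembly a single consensus copy: doubled coverage
#'     plus homozygous (consensus-error) and heterozygous (copy-divergence)
#'     variant signal over the kept copy.}
#'   \item{false_tandem_duplication}{the assembly carries two adjacent
#'     copies of a single-copy sample segment: reads are ambiguous between
#'     copies (mapping quality 0) and coverage of confidently mapped reads
#'     collapses.}
#'   \item{inversion}{pairs spanning either junction land in unexpected
#'     orientation (improperly paired).}
#'   \item{assembly_deletion}{the sample lacks a segment the assembly has
#'     (the assembly carries novel sequence): spanning pairs stretch to
#'     template lengths about `insert_mean + length`.}
#'   \item{assembly_insertion}{the sample carries a segment the assembly
#'     lacks: spanning pairs shrink to about `insert_mean - length`, reads
#'     inside the segment are unmappable.}
#'   \item{substitution_error}{the assembly consensus differs from the
#'     sample by point substitutions across the segment: homozygous
#'     non-reference calls.}
#' }
#'
#' @param kind One of `r paste(SIM_KINDS, collapse = ", ")`.
#' @param chrom Chromosome name.
#' @param position 0-based sample-coordinate anchor of the event.
#' @param length Event length in bases (> 0).
#' @param divergence Substitution rate between duplicate copies
#'   (collapsed_duplication) or between assembly and sample
#'   (substitution_error); in `[0, 0.1]`.
#' @return List of class `misassembly_spec`.
#' @export
misassembly_spec <- function(kind, chrom, position, length, divergence = 0.01) {
  kind <- match.arg(kind, SIM_KINDS)
  stopifnot(length > 0, divergence >= 0, divergence <= 0.1, position >= 0)
  structure(list(kind = kind, chrom = chrom, position = as.numeric(position),
                 length = as.numeric(length), divergence = divergence),
            class = "misassembly_spec")
}

# sample-coordinate footprint occupied by a spec (for overlap checks)
spec_footprint <- function(sp) {
  len <- switch(sp$kind,
                collapsed_duplication = 2 * sp$length,
                assembly_deletion = 1,   # insertion point only
                sp$length)
  c(sp$position, sp$position + len)
}

#' Default misassembly scenario
#'
#' One event of each detectable kind on a 500 kb chromosome: a 5 kb
#' collapsed duplication (divergence 1\%), a 5 kb false tandem duplication,
#' a 4 kb inversion, and 300 bp assembly-deletion / assembly-insertion
#' events. The indel events are sized well below the insert length so read
#' pairs can span them, which is what makes them detectable through
#' template-length shifts.
#'
#' @param chrom Chromosome name (default `"chr1"`).
#' @return List of [misassembly_spec()]s.
#' @export
default_misassemblies <- function(chrom = "chr1") {
  list(misassembly_spec("collapsed_duplication", chrom, 50000, 5000, 0.01),
       misassembly_spec("false_tandem_duplication", chrom, 150000, 5000),
       misassembly_spec("inversion", chrom, 250000, 4000),
       misassembly_spec("assembly_deletion", chrom, 330000, 300),
       misassembly_spec("assembly_insertion", chrom, 400000, 300))
}

## ---- genome ----------------------------------------------------------------

random_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Generate a random sample genome with controllable regional GC
#'
#' Bases are drawn independently with `P(G or C)` equal to the target GC
#' fraction of the region (the baseline `base_gc` outside any `gc_profile`
#' region). Deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (`DNAStringSet`) and `layout`
#'   ([genome_layout()]).
#' @export
make_sample_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  layout <- genome_layout(config$chrom_lengths)
  seqs <- lapply(names(layout), function(chr) {
    len <- as.numeric(layout[[chr]])
    prof <- config$gc_profile
    if (!is.null(prof)) prof <- prof[prof$chrom == chr, , drop = FALSE]
    if (is.null(prof) || nrow(prof) == 0) return(random_dna(len, config$base_gc))
    prof <- prof[order(prof$start), , drop = FALSE]
    parts <- character(0); cur <- 0
    for (i in seq_len(nrow(prof))) {
      if (prof$start[i] > cur)
        parts <- c(parts, random_dna(prof$start[i] - cur, config$base_gc))
      parts <- c(parts, random_dna(prof$end[i] - prof$start[i], prof$gc[i]))
      cur <- prof$end[i]
    }
    if (cur < len) parts <- c(parts, random_dna(len - cur, config$base_gc))
    paste(parts, collapse = "")
  })
  genome <- Biostrings::DNAStringSet(unlist(seqs))
  names(genome) <- names(layout)
  list(genome = genome, layout = layout)
}

# substitute bases at rate `rate`; returns list(seq, at = 1-based positions)
mutate_seq <- function(dna, rate) {
  n <- length(dna)
  at <- which(stats::runif(n) < rate)
  if (length(at) == 0) return(list(seq = dna, at = integer(0)))
  bases <- c("A", "C", "G", "T")
  cur <- match(as.character(Biostrings::extractAt(dna, IRanges(at, at))), bases)
  new <- bases[((cur - 1 + sample(1:3, length(at), replace = TRUE)) %% 4) + 1]
  out <- Biostrings::replaceLetterAt(dna, at, paste(new, collapse = ""))
  list(seq = out, at = at)
}

## ---- corruption ------------------------------------------------------------

#' Plant misassemblies into an assembly derived from a sample genome
#'
#' Walks each chromosome left to right applying the (non-overlapping)
#' events, producing the corrupted assembly, a truth BED per event kind in
#' assembly coordinates, and the sample-to-assembly segment map used by
#' [project_alignments()]. For a collapsed duplication the sample itself
#' is adjusted: the second-copy segment (immediately following the kept
#' copy) is rewritten as a diverged copy of the first, and the assembly's
#' kept copy receives its own consensus substitutions at the same rate, so
#' reads produce both heterozygous (copy-divergence) and homozygous
#' (consensus-error) variant signal. The returned `sample` is therefore
#' the authoritative sequence reads are drawn from.
#'
#' @param sample_genome `DNAStringSet` from [make_sample_genome()] (or the
#'   `genome` element of its result).
#' @param specs List of [misassembly_spec()]s; footprints must not overlap.
#' @param seed Integer seed for the mutation/novel-sequence randomness.
#' @return List with `sample` (possibly adjusted `DNAStringSet`),
#'   `assembly` (`DNAStringSet`), `sample_layout`, `assembly_layout`,
#'   `segments` (`data.table` sample-to-assembly map), `truth` (named list
#'   of `GRanges` per kind, assembly coordinates), `specs`.
#' @export
corrupt_assembly <- function(sample_genome, specs = list(), seed = 1) {
  if (is.list(sample_genome) && !is.null(sample_genome$genome))
    sample_genome <- sample_genome$genome
  set.seed(seed)
  for (sp in specs) {
    stopifnot(inherits(sp, "misassembly_spec"))
    if (!sp$chrom %in% names(sample_genome))
      stop("corrupt_assembly: unknown chromosome ", sp$chrom)
    fp <- spec_footprint(sp)
    if (fp[2] > length(sample_genome[[sp$chrom]]))
      stop("corrupt_assembly: event extends past end of ", sp$chrom)
  }
  # overlap check on sample footprints, per chromosome
  for (chr in unique(vapply(specs, `[[`, "", "chrom"))) {
    fps <- do.call(rbind, lapply(specs[vapply(specs, `[[`, "", "chrom") == chr],
                                 spec_footprint))
    fps <- fps[order(fps[, 1]), , drop = FALSE]
    if (nrow(fps) > 1 && any(fps[-1, 1] < fps[-nrow(fps), 2]))
      stop("corrupt_assembly: overlapping event footprints on ", chr)
  }

  seg_rows <- list()
  truth_rows <- list()
  sample_out <- list()
  assembly_out <- list()

  for (chr in names(sample_genome)) {
    S <- sample_genome[[chr]]
    sp_chr <- specs[vapply(specs, `[[`, "", "chrom") == chr]
    sp_chr <- sp_chr[order(vapply(sp_chr, `[[`, 0, "position"))]
    scur <- 0; acur <- 0
    s_parts <- list(); a_parts <- list()
    emit_linear <- function(from, to) {
      if (to > from) {
        seg <- Biostrings::subseq(S, from + 1, to)
        s_parts[[length(s_parts) + 1]] <<- seg
        a_parts[[length(a_parts) + 1]] <<- seg
        seg_rows[[length(seg_rows) + 1]] <<- data.frame(
          chrom = chr, s_start = from, s_end = to, type = "linear",
          a_start = acur, a_start2 = NA_real_)
        acur <<- acur + (to - from)
      }
    }
    for (sp in sp_chr) {
      p <- sp$position; L <- sp$length
      emit_linear(scur, p)
      scur <- p
      if (sp$kind == "collapsed_duplication") {
        seq1 <- Biostrings::subseq(S, p + 1, p + L)
        copy2 <- mutate_seq(seq1, sp$divergence)$seq          # sample copy 2
        consensus <- mutate_seq(seq1, sp$divergence)$seq      # assembly copy
        s_parts <- c(s_parts, list(seq1, copy2))
        a_parts <- c(a_parts, list(consensus))
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          chrom = chr, s_start = p, s_end = p + L, type = "linear",
          a_start = acur, a_start2 = NA_real_)
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          chrom = chr, s_start = p + L, s_end = p + 2 * L, type = "collapse2",
          a_start = acur, a_start2 = NA_real_)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          kind = sp$kind, chrom = chr, start = acur, end = acur + L)
        acur <- acur + L; scur <- p + 2 * L
      } else if (sp$kind == "false_tandem_duplication") {
        seg <- Biostrings::subseq(S, p + 1, p + L)
        s_parts <- c(s_parts, list(seg))
        a_parts <- c(a_parts, list(seg, seg))
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          chrom = chr, s_start = p, s_end = p + L, type = "ftd",
          a_start = acur, a_start2 = acur + L)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          kind = sp$kind, chrom = chr, start = acur, end = acur + 2 * L)
        acur <- acur + 2 * L; scur <- p + L
      } else if (sp$kind == "inversion") {
        seg <- Biostrings::subseq(S, p + 1, p + L)
        s_parts <- c(s_parts, list(seg))
        a_parts <- c(a_parts, list(Biostrings::reverseComplement(seg)))
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          chrom = chr, s_start = p, s_end = p + L, type = "inv",
          a_start = acur, a_start2 = NA_real_)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          kind = sp$kind, chrom = chr, start = acur, end = acur + L)
        acur <- acur + L; scur <- p + L
      } else if (sp$kind == "assembly_deletion") {
        novel <- Biostrings::DNAString(random_dna(L, 0.5))
        a_parts <- c(a_parts, list(novel))
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          kind = sp$kind, chrom = chr, start = acur, end = acur + L)
        acur <- acur + L                 # no sample consumed
      } else if (sp$kind == "assembly_insertion") {
        seg <- Biostrings::subseq(S, p + 1, p + L)
        s_parts <- c(s_parts, list(seg))  # sample keeps it; assembly drops it
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          chrom = chr, s_start = p, s_end = p + L, type = "unmappable",
          a_start = NA_real_, a_start2 = NA_real_)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          kind = sp$kind, chrom = chr, start = max(0, acur - 1), end = acur + 1)
        scur <- p + L
      } else if (sp$kind == "substitution_error") {
        seg <- Biostrings::subseq(S, p + 1, p + L)
        s_parts <- c(s_parts, list(seg))
        a_parts <- c(a_parts, list(mutate_seq(seg, sp$divergence)$seq))
        seg_rows[[length(seg_rows) + 1]] <- data.frame(
          chrom = chr, s_start = p, s_end = p + L, type = "linear",
          a_start = acur, a_start2 = NA_real_)
        truth_rows[[length(truth_rows) + 1]] <- data.frame(
          kind = sp$kind, chrom = chr, start = acur, end = acur + L)
        acur <- acur + L; scur <- p + L
      }
    }
    emit_linear(scur, length(S))
    sample_out[[chr]] <- do.call(Biostrings::xscat,
                                 c(list(Biostrings::DNAString("")), s_parts))
    assembly_out[[chr]] <- do.call(Biostrings::xscat,
                                   c(list(Biostrings::DNAString("")), a_parts))
  }

  sample_set <- Biostrings::DNAStringSet(sample_out)
  assembly_set <- Biostrings::DNAStringSet(assembly_out)
  segments <- as.data.table(do.call(rbind, seg_rows))
  setorder(segments, chrom, s_start)
  tr <- if (length(truth_rows)) do.call(rbind, truth_rows) else
    data.frame(kind = character(0), chrom = character(0),
               start = numeric(0), end = numeric(0))
  truth <- lapply(split(tr, factor(tr$kind, levels = SIM_KINDS)), function(d) {
    if (nrow(d) == 0) GRanges() else intervals(d$chrom, d$start, d$end)
  })
  list(sample = sample_set, assembly = assembly_set,
       sample_layout = genome_layout(stats::setNames(Biostrings::width(sample_set),
                                                     names(sample_set))),
       assembly_layout = genome_layout(stats::setNames(Biostrings::width(assembly_set),
                                                       names(assembly_set))),
       segments = segments, truth = truth, specs = specs)
}

## ---- read pairs ------------------------------------------------------------

#' Simulate paired-end fragments from a sample genome
#'
#' Fragment starts are uniform over each chromosome (chromosomes weighted
#' by length), fragment lengths Normal(insert_mean, insert_sd) truncated at
#' `2 * read_length`, and per-base sequencing errors applied at
#' `error_rate`. An optional GC response curve thins fragments by their
#' own GC fraction, emulating PCR bias; `depth` is the pre-thinning
#' target.
#'
#' @param sample_genome `DNAStringSet` (use the `sample` component of
#'   [corrupt_assembly()]).
#' @param config A [sim_config()].
#' @param gc_response NULL, or a `data.frame` (`gc`, `multiplier`) of
#'   retention-probability control points interpolated linearly (constant
#'   beyond the ends), or a function of GC fraction.
#' @return `data.table` with `id`, `chrom`, `start` (0-based), `len`,
#'   `r1`, `r2` (read sequences, both given on the sample forward strand).
#' @export
simulate_pairs <- function(sample_genome, config, gc_response = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  rl <- config$read_length
  lens <- stats::setNames(Biostrings::width(sample_genome), names(sample_genome))
  total <- sum(as.numeric(lens))
  n <- round(config$depth * total / config$insert_mean)
  chrom <- sample(names(lens), n, replace = TRUE, prob = as.numeric(lens))
  flen <- pmax(2 * rl, round(stats::rnorm(n, config$insert_mean, config$insert_sd)))
  flen <- pmin(flen, as.numeric(lens[chrom]))
  start <- floor(stats::runif(n) * (as.numeric(lens[chrom]) - flen + 1))
  dt <- data.table(chrom = chrom, start = start, len = flen)

  if (!is.null(gc_response)) {
    resp <- if (is.function(gc_response)) gc_response else {
      gr_pts <- gc_response[order(gc_response$gc), ]
      function(g) stats::approx(gr_pts$gc, gr_pts$multiplier, xout = g,
                                rule = 2)$y
    }
    gcfrac <- numeric(nrow(dt))
    for (chr in unique(dt$chrom)) {
      i <- which(dt$chrom == chr)
      v <- Biostrings::extractAt(sample_genome[[chr]],
                                 IRanges(dt$start[i] + 1, dt$start[i] + dt$len[i]))
      f <- Biostrings::letterFrequency(v, c("G", "C"))
      gcfrac[i] <- rowSums(f) / dt$len[i]
    }
    keep <- stats::runif(nrow(dt)) < pmin(1, pmax(0, resp(gcfrac)))
    dt <- dt[keep]
  }

  # read sequences on the sample forward strand
  r1 <- r2 <- character(nrow(dt))
  for (chr in unique(dt$chrom)) {
    i <- which(dt$chrom == chr)
    r1[i] <- as.character(Biostrings::extractAt(
      sample_genome[[chr]], IRanges(dt$start[i] + 1, dt$start[i] + rl)))
    r2[i] <- as.character(Biostrings::extractAt(
      sample_genome[[chr]], IRanges(dt$start[i] + dt$len[i] - rl + 1,
                                    dt$start[i] + dt$len[i])))
  }
  if (config$error_rate > 0) {
    r1 <- apply_read_errors(r1, rl, config$error_rate)
    r2 <- apply_read_errors(r2, rl, config$error_rate)
  }
  dt[, `:=`(id = sprintf("frag%07d", seq_len(nrow(dt))), r1 = r1, r2 = r2)]
  dt[]
}

apply_read_errors <- function(seqs, rl, rate) {
  nerr <- stats::rbinom(length(seqs), rl, rate)
  bases <- c("A", "C", "G", "T")
  for (i in which(nerr > 0)) {
    pos <- sample.int(rl, nerr[i])
    s <- strsplit(seqs[i], "")[[1]]
    cur <- match(s[pos], bases)
    cur[is.na(cur)] <- 1L
    s[pos] <- bases[((cur - 1 + sample(1:3, length(pos), replace = TRUE)) %% 4) + 1]
    seqs[i] <- paste(s, collapse = "")
  }
  seqs
}

## ---- projection ------------------------------------------------------------

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Project simulated fragments into assembly coordinates as SAM records
#'
#' Each mate is placed through the sample-to-assembly segment map from
#' [corrupt_assembly()], using the segment containing the majority of the
#' read's bases (soft-clipping is not modelled). Reads falling mostly
#' inside sequence absent from the assembly are dropped and counted. Reads
#' wholly inside a false-tandem-duplication copy are assigned at random
#' between the two assembly copies with mapping quality 0 (mates stay
#' together); all other reads get mapping quality 60. A pair is flagged
#' properly paired (0x2) iff both mates map to one chromosome in
#' leftmost-forward / rightmost-reverse orientation with an outer template
#' length within `insert_mean +/- 4 * insert_sd`.
#'
#' @param frags Fragment table from [simulate_pairs()].
#' @param corr Result of [corrupt_assembly()].
#' @param config The [sim_config()] used for the fragments.
#' @return List with `records` (SAM record `data.table` for [write_sam()]),
#'   `n_dropped_reads`, `n_dropped_pairs` (pairs losing both mates).
#' @export
project_alignments <- function(frags, corr, config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  rl <- config$read_length
  segs <- corr$segments
  alen <- corr$assembly_layout

  n <- nrow(frags)
  # mate sample intervals (0-based)
  m_start <- cbind(frags$start, frags$start + frags$len - rl)
  # per-fragment FTD copy assignment (used only if wholly inside an ftd seg)
  ftd_copy <- 1L + stats::rbinom(n, 1L, 0.5)

  place <- matrix(NA_real_, n, 2)       # assembly 0-based start
  flip <- matrix(FALSE, n, 2)           # strand flipped by inversion
  mapq <- matrix(60L, n, 2)
  mapped <- matrix(TRUE, n, 2)

  for (chr in unique(frags$chrom)) {
    sc <- segs[segs$chrom == chr]
    fi <- which(frags$chrom == chr)
    for (m in 1:2) {
      s <- m_start[fi, m]
      mid <- s + rl / 2
      si <- findInterval(mid, sc$s_start)
      si[si < 1] <- 1L
      type <- sc$type[si]
      a0 <- sc$a_start[si]
      off_in_seg <- s - sc$s_start[si]
      ast <- rep(NA_real_, length(fi))

      lin <- type %in% c("linear", "collapse2")
      ast[lin] <- a0[lin] + off_in_seg[lin]

      inv <- type == "inv"
      ast[inv] <- a0[inv] + (sc$s_end[si][inv] - (s[inv] + rl))
      flip[fi[inv], m] <- TRUE

      ftd <- type == "ftd"
      if (any(ftd)) {
        k <- fi[ftd]
        seg_s <- sc$s_start[si][ftd]; seg_e <- sc$s_end[si][ftd]
        whole <- frags$start[k] >= seg_s & (frags$start[k] + frags$len[k]) <= seg_e
        copy2 <- (whole & ftd_copy[k] == 2L) |
          (!whole & (frags$start[k] + frags$len[k]) > seg_e)
        base <- ifelse(copy2, sc$a_start2[si][ftd], a0[ftd])
        ast[ftd] <- base + off_in_seg[ftd]
        mapq[k[whole], m] <- 0L
      }

      # reads mostly inside sample-only sequence: dropped only when fully
      # inside; otherwise anchored to the side holding the majority of
      # their mappable bases (aligner-like junction placement)
      unm <- which(type == "unmappable")
      for (j in unm) {
        s_j <- s[j]
        seg_s <- sc$s_start[si[j]]; seg_e <- sc$s_end[si[j]]
        left_bases <- max(0, seg_s - s_j)
        right_bases <- max(0, s_j + rl - seg_e)
        if (left_bases == 0 && right_bases == 0) {
          mapped[fi[j], m] <- FALSE
          next
        }
        use_left <- left_bases >= right_bases && si[j] > 1L
        nb <- if (use_left) si[j] - 1L else min(si[j] + 1L, nrow(sc))
        if (sc$type[nb] == "unmappable") { mapped[fi[j], m] <- FALSE; next }
        if (sc$type[nb] == "inv") {
          ast[j] <- sc$a_start[nb] + (sc$s_end[nb] - (s_j + rl))
          flip[fi[j], m] <- TRUE
        } else {
          base <- if (sc$type[nb] == "ftd" && use_left)
            sc$a_start2[nb] else sc$a_start[nb]
          ast[j] <- base + (s_j - sc$s_start[nb])
        }
      }

      # clamp placements into the assembly chromosome
      ok <- !is.na(ast)
      ast[ok] <- pmin(pmax(ast[ok], 0), as.numeric(alen[[chr]]) - rl)
      place[fi, m] <- ast
    }
  }

  # strand in assembly: mate1 sample-forward, mate2 sample-reverse
  strand_rev <- cbind(flip[, 1], !flip[, 2])   # TRUE = reverse in assembly

  both <- mapped[, 1] & mapped[, 2]
  one <- xor(mapped[, 1], mapped[, 2])
  n_dropped_reads <- sum(!mapped)
  n_dropped_pairs <- sum(!mapped[, 1] & !mapped[, 2])

  # properness for fully mapped pairs
  a1 <- place[, 1]; a2 <- place[, 2]
  outer_l <- pmin(a1, a2); outer_r <- pmax(a1, a2) + rl
  tlen_abs <- outer_r - outer_l
  fwd_mate <- ifelse(strand_rev[, 1] & !strand_rev[, 2], 2L,
                     ifelse(!strand_rev[, 1] & strand_rev[, 2], 1L, 0L))
  fr_ok <- fwd_mate != 0L &
    ifelse(fwd_mate == 1L, a1 <= a2, a2 <= a1)
  dist_ok <- tlen_abs >= config$insert_mean - 4 * config$insert_sd &
    tlen_abs <= config$insert_mean + 4 * config$insert_sd
  proper <- both & fr_ok & dist_ok

  recs <- list()
  for (m in 1:2) {
    o <- 3 - m
    use <- mapped[, m]
    if (!any(use)) next
    flag <- 1L +                                     # paired
      ifelse(proper[use], 2L, 0L) +
      ifelse(!mapped[use, o], 8L, 0L) +
      ifelse(strand_rev[use, m], 16L, 0L) +
      ifelse(mapped[use, o] & strand_rev[use, o], 32L, 0L) +
      if (m == 1L) 64L else 128L
    seqs <- if (m == 1L) frags$r1[use] else frags$r2[use]
    needs_rc <- flip[use, m]
    if (any(needs_rc)) seqs[needs_rc] <- revcomp_chr(seqs[needs_rc])
    tl <- integer(sum(use))
    bm <- both[use]
    sign <- ifelse(place[use, m] < place[use, o] |
                     (place[use, m] == place[use, o] & m == 1L), 1L, -1L)
    tl[bm] <- as.integer(sign[bm] * tlen_abs[use][bm])
    recs[[m]] <- data.table(
      qname = frags$id[use],
      flag = flag,
      chrom = frags$chrom[use],
      pos = as.integer(place[use, m] + 1L),
      mapq = mapq[use, m],
      cigar = paste0(rl, "M"),
      mchrom = ifelse(bm, "=", "*"),
      mpos = ifelse(bm, as.integer(place[use, o] + 1L), 0L),
      tlen = tl,
      seq = seqs,
      qual = strrep("I", rl)
    )
  }
  list(records = data.table::rbindlist(recs),
       n_dropped_reads = n_dropped_reads,
       n_dropped_pairs = n_dropped_pairs)
}

## ---- truth evaluation ------------------------------------------------------

#' Base-level precision and recall of a flagged track against truth
#'
#' @param flagged,truth `GRanges` in the same (assembly) coordinates.
#' @return List with `recall`, `precision` (1 when nothing is flagged,
#'   with `flagged_bases = 0`), `truth_bases`, `flagged_bases`,
#'   `overlap_bases`.
#' @export
evaluate_track <- function(flagged, truth) {
  fm <- merge_intervals(flagged); tm <- merge_intervals(truth)
  ov <- intersect_sets(tm, fm)$overlap_bases
  tb <- total_bases(tm); fb <- total_bases(fm)
  list(recall = if (tb == 0) 1 else ov / tb,
       precision = if (fb == 0) 1 else ov / fb,
       truth_bases = tb, flagged_bases = fb, overlap_bases = ov)
}

#' Evaluate evidence tracks against planted-misassembly truth
#'
#' Matches each planted kind with the evidence track expected to detect it:
#' collapsed duplication with high coverage, false tandem duplication with
#' the union of low coverage and multimapper regions, inversion with
#' improper pairing, assembly deletion with large inserts, assembly
#' insertion with small inserts, substitution errors with homozygous
#' variants. For inversions the target bases are the two breakpoint
#' neighbourhoods (junction +/- `breakpoint_pad`), because pairs fully
#' inside an inverted segment remain properly oriented and the paired-end
#' signature exists only at the junctions.
#'
#' @param flagged Named list of evidence `GRanges`: `high_cov`, `low_cov`,
#'   `multimap`, `improper_pair`, `large_insert`, `small_insert`,
#'   `hom_variant` (missing entries treated as empty).
#' @param truth Named list of truth `GRanges` from [corrupt_assembly()].
#' @param layout Assembly [genome_layout()] (for breakpoint clipping).
#' @param breakpoint_pad Half-width of inversion breakpoint targets
#'   (default 427 bp, the insert mean).
#' @return `data.frame` with `kind`, `track`, `truth_bases`,
#'   `flagged_bases`, `recall`, `precision`.
#' @export
evaluate_misassemblies <- function(flagged, truth, layout,
                                   breakpoint_pad = 427) {
  g <- function(nm) if (!is.null(flagged[[nm]])) flagged[[nm]] else GRanges()
  track_for <- list(
    collapsed_duplication = list(name = "HIGH_COV", gr = g("high_cov")),
    false_tandem_duplication = list(
      name = "LC/MULTIMAP",
      gr = merge_intervals(suppressWarnings(c(
        GRanges(seqnames(g("low_cov")), IRanges::ranges(g("low_cov"))),
        GRanges(seqnames(g("multimap")), IRanges::ranges(g("multimap"))))))),
    inversion = list(name = "IMPROPER_PAIR", gr = g("improper_pair")),
    assembly_deletion = list(name = "LARGE_INSERT", gr = g("large_insert")),
    assembly_insertion = list(name = "SMALL_INSERT", gr = g("small_insert")),
    substitution_error = list(name = "HOM_VARIANT", gr = g("hom_variant")))
  rows <- list()
  for (kind in names(truth)) {
    tr <- truth[[kind]]
    if (length(tr) == 0) next
    if (kind == "inversion") {
      chr <- as.character(seqnames(tr))
      bp <- c(start(tr) - 1L, end(tr))      # 0-based junction offsets
      chr2 <- c(chr, chr)
      tr <- intervals(chr2,
                      pmax(0, bp - breakpoint_pad),
                      pmin(as.numeric(layout[chr2]), bp + breakpoint_pad))
      tr <- merge_intervals(tr)
    }
    tk <- track_for[[kind]]
    ev <- evaluate_track(tk$gr, tr)
    rows[[kind]] <- data.frame(kind = kind, track = tk$name,
                               truth_bases = ev$truth_bases,
                               flagged_bases = ev$flagged_bases,
                               recall = ev$recall, precision = ev$precision)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## ---- top-level simulation --------------------------------------------------

#' Run a full simulation and write its artifacts
#'
#' Generates the sample genome, plants the misassemblies, simulates and
#' projects read pairs, and writes `sample.fa`, `assembly.fa`,
#' `reads.sam` (coordinate-sorted), `assembly.chrom.sizes`, `gaps.bed`
#' (empty), `truth_<kind>.bed` files, and `sim_config.yaml` to `outdir`.
#' Fully deterministic under `config$seed`.
#'
#' @param config A [sim_config()].
#' @param specs List of [misassembly_spec()]s (default:
#'   [default_misassemblies()]; use `list()` for an uncorrupted control).
#' @param outdir Output directory (created if needed).
#' @param gc_response Optional GC response (see [simulate_pairs()]).
#' @return Invisibly, a list with the in-memory objects (`corr`, `frags`,
#'   `proj`, `paths`).
#' @export
run_simulation <- function(config = sim_config(),
                           specs = default_misassemblies(),
                           outdir, gc_response = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sg <- make_sample_genome(config)
  corr <- corrupt_assembly(sg$genome, specs, seed = config$seed + 1L)
  frags <- simulate_pairs(corr$sample, config, gc_response = gc_response)
  proj <- project_alignments(frags, corr, config)
  paths <- list(sample_fa = file.path(outdir, "sample.fa"),
                assembly_fa = file.path(outdir, "assembly.fa"),
                reads_sam = file.path(outdir, "reads.sam"),
                chrom_sizes = file.path(outdir, "assembly.chrom.sizes"),
                gaps_bed = file.path(outdir, "gaps.bed"),
                config_yaml = file.path(outdir, "sim_config.yaml"))
  Biostrings::writeXStringSet(corr$sample, paths$sample_fa)
  Biostrings::writeXStringSet(corr$assembly, paths$assembly_fa)
  write_sam(proj$records, corr$assembly_layout, paths$reads_sam)
  write_chrom_sizes(corr$assembly_layout, paths$chrom_sizes)
  file.create(paths$gaps_bed)
  for (kind in names(corr$truth)) {
    if (length(corr$truth[[kind]]) > 0) {
      paths[[paste0("truth_", kind)]] <- file.path(outdir, paste0("truth_", kind, ".bed"))
      write_bed(corr$truth[[kind]], paths[[paste0("truth_", kind)]])
    }
  }
  cfg <- config; class(cfg) <- NULL
  cfg$gc_profile <- if (is.null(cfg$gc_profile)) NULL else as.list(cfg$gc_profile)
  yaml::write_yaml(cfg, paths$config_yaml)
  invisible(list(corr = corr, frags = frags, proj = proj, paths = paths))
}
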