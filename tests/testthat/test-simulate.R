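# smaller-than-default configurations keep these unit tests fast; the full
# default scenario is exercised in test-acceptance.R

test_that("sample genome generation is deterministic with regional GC", {
  cfg <- sim_config(seed = 1, chrom_lengths = c(chr1 = 20000),
                    gc_profile = data.frame(chrom = "chr1", start = 0,
                                            end = 10000, gc = 0.6))
  g1 <- make_sample_genome(cfg)
  g2 <- make_sample_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))

  gc_region <- Biostrings::letterFrequency(
    Biostrings::subseq(g1$genome[[1]], 1, 10000), c("G", "C"))
  expect_lt(abs(sum(gc_region) / 10000 - 0.6), 0.03)
  gc_rest <- Biostrings::letterFrequency(
    Biostrings::subseq(g1$genome[[1]], 10001, 20000), c("G", "C"))
  expect_lt(abs(sum(gc_rest) / 10000 - 0.5), 0.03)

  expect_error(sim_config(seed = 1, chrom_lengths = c(chr1 = 0)))
})

test_that("corruption: identity without specs; events reshape the assembly", {
  cfg <- sim_config(seed = 5, chrom_lengths = c(chr1 = 60000))
  g <- make_sample_genome(cfg)
  corr0 <- corrupt_assembly(g$genome, list(), seed = 6)
  expect_identical(as.character(corr0$assembly), as.character(corr0$sample))
  expect_true(all(lengths(corr0$truth) == 0))

  specs <- list(misassembly_spec("collapsed_duplication", "chr1", 10000, 5000,
                                 divergence = 0.01),
                misassembly_spec("inversion", "chr1", 30000, 4000))
  corr <- corrupt_assembly(g$genome, specs, seed = 6)
  # collapse: assembly loses one copy -> 5 kb shorter than the sample
  expect_equal(length(corr$sample[[1]]) - length(corr$assembly[[1]]), 5000L)
  # inversion: length unchanged, truth interval is the full 4 kb
  tr_inv <- corr$truth$inversion
  expect_equal(width(tr_inv), 4000L)
  # ~50 consensus substitutions inside the kept collapse copy
  tr_col <- corr$truth$collapsed_duplication
  kept_asm <- Biostrings::extractAt(corr$assembly[[1]],
                                    IRanges::ranges(tr_col))[[1]]
  copy1 <- Biostrings::extractAt(corr$sample[[1]],
                                 IRanges::IRanges(10001, 15000))[[1]]
  n_div <- sum(charToRaw(as.character(kept_asm)) != charToRaw(as.character(copy1)))
  expect_gt(n_div, 20)
  expect_lt(n_div, 90)

  over <- list(misassembly_spec("inversion", "chr1", 10000, 5000),
               misassembly_spec("false_tandem_duplication", "chr1", 12000, 5000))
  expect_error(corrupt_assembly(g$genome, over, seed = 6), "overlap")
})

test_that("simulated pairs hit the target depth; zero error rate is exact", {
  cfg <- sim_config(seed = 3, chrom_lengths = c(chr1 = 100000), depth = 40,
                    error_rate = 0)
  g <- make_sample_genome(cfg)
  fr <- simulate_pairs(g$genome, cfg)
  expect_identical(fr, simulate_pairs(g$genome, cfg))  # determinism
  realized <- sum(as.numeric(fr$len)) / 100000
  expect_lt(abs(realized - 40), 2)
  # error-free reads match the genome exactly
  idx <- sample(nrow(fr), 50)
  r1_true <- as.character(Biostrings::extractAt(
    g$genome[[1]], IRanges::IRanges(fr$start[idx] + 1, fr$start[idx] + 100)))
  expect_identical(fr$r1[idx], r1_true)
})

test_that("projection of an uncorrupted genome is fully proper and uniform", {
  cfg <- sim_config(seed = 4, chrom_lengths = c(chr1 = 80000), depth = 20)
  g <- make_sample_genome(cfg)
  corr <- corrupt_assembly(g$genome, list(), seed = 5)
  fr <- simulate_pairs(corr$sample, cfg)
  proj <- project_alignments(fr, corr, cfg)
  expect_equal(proj$n_dropped_reads, 0L)
  expect_equal(nrow(proj$records), 2L * nrow(fr))   # mass conservation
  # essentially all pairs proper (fragments beyond the 4-SD distance
  # window are legitimately flagged improper, as an aligner would)
  expect_gt(mean(bitwAnd(proj$records$flag, 2L) > 0), 0.999)
  expect_true(all(proj$records$mapq == 60L))
  expect_equal(sort(unique(abs(proj$records$tlen))), sort(unique(fr$len)))
})

test_that("projection plants the documented pair signatures", {
  cfg <- sim_config(seed = 8, chrom_lengths = c(chr1 = 100000), depth = 30)
  g <- make_sample_genome(cfg)
  specs <- list(misassembly_spec("false_tandem_duplication", "chr1", 20000, 4000),
                misassembly_spec("assembly_deletion", "chr1", 50000, 300),
                misassembly_spec("assembly_insertion", "chr1", 80000, 300))
  corr <- corrupt_assembly(g$genome, specs, seed = 9)
  fr <- simulate_pairs(corr$sample, cfg)
  proj <- project_alignments(fr, corr, cfg)
  rec <- proj$records

  # reads wholly inside a false-tandem copy are mapq-0 and split over copies
  ftd <- corr$truth$false_tandem_duplication
  in_ftd <- rec$pos >= start(ftd) & rec$pos + 100 <= end(ftd)
  expect_gt(sum(rec$mapq[in_ftd] == 0), 0.7 * sum(in_ftd))
  copy1 <- rec$pos[in_ftd] < start(ftd) + 4000
  expect_gt(mean(copy1), 0.3); expect_lt(mean(copy1), 0.7)

  # pairs spanning the assembly-only segment stretch by ~ +300
  del <- corr$truth$assembly_deletion
  span_del <- rec$tlen > 0 & rec$pos < start(del) & rec$pos + rec$tlen > end(del)
  expect_gt(sum(span_del), 5)
  expect_gt(median(rec$tlen[span_del]), cfg$insert_mean + 200)

  # pairs spanning the sample-only segment shrink by ~ -300
  ins <- corr$truth$assembly_insertion
  near_ins <- rec$tlen > 0 & rec$pos < start(ins) &
    rec$pos + rec$tlen > end(ins)
  shrunk <- near_ins & rec$tlen < cfg$insert_mean - 2 * cfg$insert_sd
  expect_gt(sum(shrunk), 5)
})

test_that("truth evaluation scores flagged tracks against planted truth", {
  truth <- list(collapsed_duplication = gr1(1000, 2000))
  lay <- genome_layout(c(chr1 = 10000))
  ev <- evaluate_misassemblies(list(high_cov = gr1(1000, 2000)), truth, lay)
  expect_equal(ev$recall, 1)
  expect_equal(ev$precision, 1)
  ev0 <- evaluate_misassemblies(list(high_cov = GRanges()), truth, lay)
  expect_equal(ev0$recall, 0)
  expect_equal(ev0$precision, 1)     # nothing flagged, by convention
  expect_equal(ev0$flagged_bases, 0)
})

test_that("run_simulation writes a complete, reproducible artifact set", {
  cfg <- sim_config(seed = 11, chrom_lengths = c(chr1 = 60000), depth = 15)
  specs <- list(misassembly_spec("inversion", "chr1", 30000, 3000))
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  run_simulation(cfg, specs, outdir = d1)
  run_simulation(cfg, specs, outdir = d2)
  for (fn in c("sample.fa", "assembly.fa", "reads.sam", "gaps.bed",
               "assembly.chrom.sizes", "truth_inversion.bed",
               "sim_config.yaml")) {
    expect_true(file.exists(file.path(d1, fn)), label = fn)
    expect_identical(unname(tools::md5sum(file.path(d1, fn))),
                     unname(tools::md5sum(file.path(d2, fn))),
                     label = paste("determinism of", fn))
  }
})
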