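## Pipeline orchestration: shared parameter set, full detector chain, and
## subcommand dispatch for the command-line front-end (inst/cli/asmqc.R).

#' Default pipeline parameters
#'
#' All defaults follow the published method: 1000 bp windows (step 1000
#' for coverage, step 800 for the pair-based tracks so consecutive windows
#' share 200 bp), mapping-quality floor 2, 2-SD cutoffs everywhere,
#' multimapper-dominance threshold 50\%, and 100 bp homozygous-variant
#' flanks.
#'
#' @param window_width Window width in bp (default 1000).
#' @param cov_step Step for coverage/multimapper windows (default 1000).
#' @param pair_step Step for insert/pairing windows (default 800).
#' @param min_mapq Mapping-quality floor for fragment extraction (default 2).
#' @param k SD multiplier for every threshold (default 2).
#' @param multimap_pct Multimapper-dominance threshold in percent
#'   (default 50).
#' @param flank Homozygous-variant flank in bp (default 100).
#' @param min_bin_windows Minimum windows per GC bin (default 50).
#' @param excluded_chroms Chromosomes dropped from analysis and from the
#'   genome-size denominator (e.g. `"chrY"` for a female individual).
#' @param caller_min_depth,caller_min_alt_fraction,caller_min_baseq
#'   Internal homozygous-site caller thresholds.
#' @return List of class `asmqc_params`.
#' @export
asmqc_params <- function(window_width = 1000, cov_step = 1000, pair_step = 800,
                         min_mapq = 2, k = 2, multimap_pct = 50, flank = 100,
                         min_bin_windows = 50, excluded_chroms = character(0),
                         caller_min_depth = 8, caller_min_alt_fraction = 0.9,
                         caller_min_baseq = 13) {
  stopifnot(window_width > 0, cov_step > 0, cov_step <= window_width,
            pair_step > 0, pair_step <= window_width, min_mapq >= 0, k > 0,
            multimap_pct >= 0, multimap_pct <= 100, flank >= 0)
  structure(as.list(environment()), class = "asmqc_params")
}

#' Run the full low-confidence-region detection chain
#'
#' From a coordinate-sorted SAM/BAM of the reference individual's
#' paired-end reads mapped to its own assembly, computes every evidence
#' track and assembles the LQ / LC / LQLC region sets:
#' \enumerate{
#'   \item fragment spans of properly paired, mapq >= 2 pairs; per-base
#'     fragment depth; per-window median coverage on gap-free 1 kb windows;
#'   \item GC normalization by the per-GC-bin median ratio; robust-normal
#'     fit; HIGH/LOW labels at mean +/- k SD;
#'   \item multimapper-dominated windows (> 50\% mapq-0 reads);
#'   \item insert-size model; per-window small/large-insert and
#'     proper-pairing percentages on overlapping windows; 2-SD fraction
#'     thresholds; flagged regions;
#'   \item homozygous non-reference sites (from `vcf` if given, otherwise
#'     the internal caller) expanded by +/- 100 bp;
#'   \item LQ = high coverage + insert/pairing anomalies + homozygous
#'     flanks; LC = low coverage; LQLC = their union.
#' }
#'
#' @param alignments Path to SAM/BAM.
#' @param assembly Path to the assembly FASTA (or a `DNAStringSet`).
#' @param gaps Assembly gap track: BED path, `GRanges`, or NULL.
#' @param vcf Optional single-sample VCF path; when NULL homozygous sites
#'   are called internally from the alignments.
#' @param params An [asmqc_params()] list.
#' @return List of class `asmqc_result` with components `layout`, `tracks`
#'   (named evidence `GRanges`), `lq`, `lc`, `lqlc`, `tables` (per-window
#'   metric tables), `models` (GC model, robust normal, insert model,
#'   fraction thresholds), `summaries`, `attribution`.
#' @export
detect_regions <- function(alignments, assembly, gaps = NULL, vcf = NULL,
                           params = asmqc_params()) {
  bam <- open_alignments(alignments)
  if (is.character(assembly)) assembly <- Biostrings::readDNAStringSet(assembly)
  names(assembly) <- sub("\\s.*$", "", names(assembly))
  layout_full <- genome_layout(stats::setNames(Biostrings::width(assembly),
                                               names(assembly)))
  keep_chr <- setdiff(names(layout_full), params$excluded_chroms)
  layout <- genome_layout(stats::setNames(as.numeric(layout_full[keep_chr]),
                                          keep_chr))
  reads <- read_alignments(bam)
  reads <- reads[reads$chrom %in% keep_chr, ]
  if (is.character(gaps)) gaps <- read_bed(gaps)
  if (is.null(gaps)) gaps <- GRanges()

  ## coverage track -----------------------------------------------------
  cov_windows <- remove_gap_windows(
    make_windows(layout, params$window_width, params$cov_step), gaps)
  frags <- extract_fragments(reads, min_mapq = params$min_mapq,
                             require_proper = TRUE)
  depth <- fragment_depth(frags, layout)
  wc <- window_median_coverage(depth, cov_windows)
  wc$gc_pct <- gc_percent(assembly, cov_windows)
  gc_model <- fit_gc_model(wc, min_bin_windows = params$min_bin_windows)
  wc <- gc_normalize(wc, gc_model)
  cov_model <- fit_robust_normal(wc$norm_cov, k = params$k)
  wc$label <- classify_coverage(wc$norm_cov, cov_model)
  high_cov <- merge_intervals(cov_windows[wc$label == "HIGH"])
  low_cov <- merge_intervals(cov_windows[wc$label == "LOW"])

  ## multimappers -------------------------------------------------------
  mm <- multimap_windows(reads, cov_windows, threshold_pct = params$multimap_pct)

  ## insert sizes / pairing ---------------------------------------------
  pair_windows <- remove_gap_windows(
    make_windows(layout, params$window_width, params$pair_step), gaps)
  ins_model <- fit_insert_model(reads)
  ins_frac <- abnormal_insert_fractions(reads, ins_model, pair_windows)
  pp_frac <- proper_pair_fractions(reads, pair_windows)
  thr_small <- fit_fraction_threshold(ins_frac$small, "above", k = params$k)
  thr_large <- fit_fraction_threshold(ins_frac$large, "above", k = params$k)
  thr_proper <- fit_fraction_threshold(pp_frac, "below", k = params$k)
  small_insert <- flag_windows(ins_frac$small, thr_small)
  large_insert <- flag_windows(ins_frac$large, thr_large)
  improper_pair <- flag_windows(pp_frac, thr_proper)

  ## homozygous variants ------------------------------------------------
  sites <- if (!is.null(vcf)) load_variants(vcf) else
    call_homozygous_sites(bam, assembly,
                          min_depth = params$caller_min_depth,
                          min_alt_fraction = params$caller_min_alt_fraction,
                          min_baseq = params$caller_min_baseq,
                          min_mapq = params$min_mapq)
  sites <- sites[sites$chrom %in% keep_chr, , drop = FALSE]
  hom_variant <- homozygous_regions(sites, layout, flank = params$flank)

  ## merge --------------------------------------------------------------
  lq <- build_lq(high_cov, small_insert, large_insert, improper_pair, hom_variant)
  lc <- build_lc(low_cov)
  lqlc <- build_lqlc(lq, lc)
  tracks <- list(high_cov = high_cov, low_cov = low_cov,
                 multimap = mm$flagged, small_insert = small_insert,
                 large_insert = large_insert, improper_pair = improper_pair,
                 hom_variant = hom_variant)
  summaries <- lapply(c(tracks, list(lq = lq, lc = lc, lqlc = lqlc)),
                      summarize_regions, layout = layout)
  structure(list(layout = layout, tracks = tracks, lq = lq, lc = lc,
                 lqlc = lqlc,
                 tables = list(window_coverage = wc,
                               multimap = mm$table,
                               small_insert = ins_frac$small,
                               large_insert = ins_frac$large,
                               proper_pair = pp_frac,
                               variant_sites = sites),
                 models = list(gc = gc_model, coverage = cov_model,
                               insert = ins_model,
                               thresholds = list(small = thr_small,
                                                 large = thr_large,
                                                 proper = thr_proper)),
                 summaries = summaries,
                 attribution = lc_attribution(lc, mm$flagged, mm$table)),
            class = "asmqc_result")
}

#' @export
print.asmqc_result <- function(x, ...) {
  cat("asmqc_result over", format(layout_size(x$layout), big.mark = ","),
      "assembly bases\n")
  for (nm in c("lq", "lc", "lqlc")) {
    s <- x$summaries[[nm]]
    cat(sprintf("  %-4s %6d features, mean %7.0f bp, %.2f%% of genome\n",
                toupper(nm), s$n_features, s$mean_size, s$pct_genome))
  }
  invisible(x)
}

#' Write the artifacts of a detection run
#'
#' Writes the three region tracks (`lq.bed` with evidence reasons in
#' column 4, `lc.bed`, `lqlc.bed`), per-evidence BEDs, the per-window
#' metric tables (TSV), and a Table-1-style `summary.tsv`.
#'
#' @param result An `asmqc_result` from [detect_regions()].
#' @param outdir Output directory.
#' @return Invisibly, the vector of written paths.
#' @export
write_results <- function(result, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  w <- function(gr, nm, name = NULL) {
    p <- file.path(outdir, nm); write_bed(gr, p, name = name); paths <<- c(paths, p)
  }
  w(result$lq, "lq.bed",
    name = if (length(result$lq)) mcols(result$lq)$reasons else NULL)
  w(result$lc, "lc.bed")
  w(result$lqlc, "lqlc.bed")
  for (nm in names(result$tracks)) w(result$tracks[[nm]], paste0(nm, ".bed"))
  for (nm in names(result$tables)) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    utils::write.table(result$tables[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  sm <- do.call(rbind, lapply(names(result$summaries), function(nm) {
    s <- result$summaries[[nm]]
    data.frame(track = nm, n_features = s$n_features,
               mean_size = round(s$mean_size),
               total_bases = s$total_bases,
               pct_genome = round(s$pct_genome, 2))
  }))
  p <- file.path(outdir, "summary.tsv")
  utils::write.table(sm, p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}

#' Overlap reports for a set of annotation BEDs
#'
#' @param result An `asmqc_result`.
#' @param annotations Named list: each element a list with `path` (BED) or
#'   `gr` (`GRanges`) and `mode` (`"feature_count"` or `"base_count"`).
#' @param outdir Optional directory to write `overlap.tsv` into.
#' @return `data.frame` mirroring the annotation-overlap table layout.
#' @export
report_overlaps <- function(result, annotations, outdir = NULL) {
  rows <- lapply(names(annotations), function(nm) {
    a <- annotations[[nm]]
    gr <- if (!is.null(a$gr)) a$gr else read_bed(a$path)
    gr <- gr[as.character(seqnames(gr)) %in% names(result$layout)]
    rep <- overlap_report(gr, result$lq, result$lc, result$lqlc,
                          mode = a$mode, name = nm)
    data.frame(annotation = nm, mode = rep$mode, total = rep$total,
               in_lq = rep$in_lq, pct_lq = round(rep$pct_lq, 2),
               in_lc = rep$in_lc, pct_lc = round(rep$pct_lc, 2),
               in_lqlc = rep$in_lqlc, pct_lqlc = round(rep$pct_lqlc, 2))
  })
  out <- do.call(rbind, rows)
  if (!is.null(outdir)) {
    utils::write.table(out, file.path(outdir, "overlap.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  out
}

## ---- config / subcommands --------------------------------------------------

#' Read a pipeline configuration file (YAML)
#'
#' Recognized keys: `paths` (alignments, assembly, gaps, vcf, outdir,
#' annotations: named list of `{path, mode}`), `params` (any
#' [asmqc_params()] argument), `sim` (any [sim_config()] argument), `seed`.
#'
#' @param path YAML file path.
#' @return List with `paths`, `params` (an `asmqc_params`), `sim`
#'   (a `sim_config`), `seed`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  seed <- if (!is.null(cfg$seed)) as.integer(cfg$seed) else 42L
  params <- do.call(asmqc_params, cfg$params %||% list())
  sim_args <- cfg$sim %||% list()
  if (!is.null(sim_args$chrom_lengths))
    sim_args$chrom_lengths <- unlist(sim_args$chrom_lengths)
  if (is.null(sim_args$seed)) sim_args$seed <- seed
  sim <- do.call(sim_config, sim_args)
  list(paths = cfg$paths %||% list(), params = params, sim = sim, seed = seed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

require_path <- function(paths, key, sub) {
  p <- paths[[key]]
  if (is.null(p) || !file.exists(p))
    stop("subcommand '", sub, "': missing required input '", key, "'",
         if (!is.null(p)) paste0(" (", p, " not found)") else "")
  p
}

provenance_log <- function(outdir, config_path, inputs) {
  inputs <- inputs[!vapply(inputs, is.null, NA)]
  inputs <- inputs[vapply(inputs, function(p) is.character(p) && file.exists(p), NA)]
  lines <- c(
    paste0("asmqc ", as.character(utils::packageVersion("asmqc"))),
    paste0("date: ", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    if (!is.null(config_path) && file.exists(config_path))
      paste0("config md5: ", unname(tools::md5sum(config_path))),
    vapply(names(inputs), function(nm)
      paste0("input ", nm, " md5: ", unname(tools::md5sum(inputs[[nm]]))), "")
  )
  writeLines(lines, file.path(outdir, "run.log"))
}

#' Run one pipeline subcommand
#'
#' Subcommands: `simulate` (write a synthetic dataset), `coverage`,
#' `inserts`, `pairing`, `variants`, `multimap` (individual evidence
#' tracks), `merge` (LQ/LC/LQLC from a full detection run), `report`
#' (annotation overlaps), `all` (everything). Every run writes a
#' provenance log (`run.log`) with package version and input checksums.
#' Outputs are pure functions of the inputs and configuration; re-running
#' reproduces them byte for byte.
#'
#' @param name Subcommand name.
#' @param config A configuration list from [read_pipeline_config()], or a
#'   path to a YAML config file.
#' @param outdir Output directory (overrides the config's).
#' @return Invisibly, the result object of the step (if any).
#' @export
run_subcommand <- function(name = c("simulate", "coverage", "inserts",
                                    "pairing", "variants", "multimap",
                                    "merge", "report", "all"),
                           config, outdir = NULL) {
  name <- match.arg(name)
  config_path <- NULL
  if (is.character(config)) { config_path <- config; config <- read_pipeline_config(config) }
  paths <- config$paths
  outdir <- outdir %||% paths$outdir %||% stop("run_subcommand: no outdir given")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  if (name == "simulate") {
    sim <- run_simulation(config$sim, outdir = outdir)
    provenance_log(outdir, config_path, list())
    return(invisible(sim))
  }

  aln <- require_path(paths, "alignments", name)
  asm <- require_path(paths, "assembly", name)
  gaps <- paths$gaps
  vcf <- paths$vcf
  provenance_log(outdir, config_path,
                 list(alignments = aln, assembly = asm, gaps = gaps, vcf = vcf))
  res <- detect_regions(aln, asm, gaps = gaps, vcf = vcf, params = config$params)

  if (name %in% c("merge", "all")) write_results(res, outdir)
  else {
    sel <- switch(name,
                  coverage = c("high_cov", "low_cov"),
                  inserts = c("small_insert", "large_insert"),
                  pairing = "improper_pair",
                  variants = "hom_variant",
                  multimap = "multimap",
                  report = character(0))
    for (nm in sel) write_bed(res$tracks[[nm]], file.path(outdir, paste0(nm, ".bed")))
  }
  if (name %in% c("report", "all") && !is.null(paths$annotations)) {
    ann <- lapply(paths$annotations, function(a)
      list(path = a$path, mode = a$mode %||% "feature_count"))
    report_overlaps(res, ann, outdir = outdir)
  }
  invisible(res)
}

#' Run the whole pipeline (`all` subcommand)
#' @inheritParams run_subcommand
#' @return Invisibly, the `asmqc_result`.
#' @export
run_pipeline <- function(config, outdir = NULL) {
  run_subcommand("all", config, outdir = outdir)
}
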