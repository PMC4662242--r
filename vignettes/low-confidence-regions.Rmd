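---
title: "Detecting low-confidence regions in draft assemblies from self-alignment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting low-confidence regions in draft assemblies from self-alignment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asmqc)
```

## The idea

When the paired-end reads of the very individual an assembly was built from
are mapped back to that assembly, there should be no structural variation
between reads and reference: fragment coverage should be flat (after GC
correction), insert sizes should follow the library distribution, read pairs
should be properly oriented, and no site should be homozygous for a
non-reference allele. Wherever these expectations break, the assembly — not
the biology — is the prime suspect. `asmqc` turns each expectation into an
evidence track over fixed-width windows, thresholds each track at
mean ± 2 SD, and merges the flagged windows into three BED tracks:

* **LQ** (low quality) — high normalized coverage, excess small/large insert
  fractions, depressed proper-pairing, or proximity (±100 bp) to a
  homozygous non-reference variant. These are the strongest misassembly
  signals (collapsed repeats, false joins, indel errors).
* **LC** (low coverage) — windows below the lower coverage cutoff. These may
  be misassemblies (false tandem duplications split reads over two copies)
  but also arise from poor mappability or library bias, so they are kept
  separate.
* **LQLC** — the merged union of both.

A heterozygous structural variant in the sequenced individual produces the
same signatures as a misassembly; the method is deliberately conservative
and treats such regions as low-confidence rather than attempting to
distinguish the two.

## Coverage and GC normalization

Coverage is **fragment** coverage: each retained pair (both mates mapped,
mapping quality ≥ 2, properly paired) contributes its full outer span once.
Per 1 kb window (step 1 kb, windows touching assembly gaps removed before
any model fitting), the median of the per-base depths is taken; medians
rather than means keep collapsed-repeat spikes from leaking into
neighbouring statistics.

PCR-based libraries under-represent GC-poor and GC-rich fragments, so raw
window medians are corrected by the median-ratio factor

$$ f(g) = \frac{\mathrm{median}_w\,(m_w)}{\mathrm{median}_{w:\,GC(w)=g}\,(m_w)}, \qquad
   \tilde m_w = m_w \cdot f(GC(w)) , $$

where $GC(w)$ is the window's integer GC percentage computed over
unambiguous bases only (windows of pure N have undefined GC and are left
uncorrected and out of the model). By construction the per-bin median of
$\tilde m_w$ equals the global median in every corrected bin — a fixed
point the test suite checks on a simulated GC-response dataset. Bins with
fewer than 50 windows or a zero median get $f = 1$: the ratio is unstable
there, and inflating near-empty bins does more harm than leaving them
uncorrected.

### Robust normal fit

The normalized-coverage distribution is near normal with a heavy right tail
(collapsed repeats, organelle-like sequence), which inflates the plain mean
and SD badly. `fit_robust_normal()` overlays a Gaussian on the histogram
instead: a least-squares fit of $A \exp(-(x-\mu)^2/2\sigma^2)$ to
unit-width histogram bins restricted to the 5th–95th percentile range,
refit once restricted to $\mu \pm 3\hat\sigma$. The procedure is
deterministic, ignores tail mass entirely, and on
Normal(41, 7) samples with 2 % contamination at 200–400 recovers both
moments within 0.5 while the sample SD exceeds 37. Windows are labelled
HIGH above $\mu + k\sigma$ and LOW below $\mu - k\sigma$ ($k = 2$ by
default); inequalities are strict, so a window exactly at a cutoff is
NORMAL.

## Insert sizes and pairing

The insert model is the mean and SD of the absolute template length of
properly paired FR reads after discarding values above 10× the median —
a deterministic stand-in for the version-dependent trimming of the usual
insert-metrics tools that leaves symmetric ±2 SD cutoffs intact. Per
overlapping window (width 1000, step 800), the package computes the
percentage of overlapping reads (any overlap of the read's own aligned
span; mates are not double-counted into each other's windows) that are
abnormally small, abnormally large, or properly paired, using the
**original, unfiltered** alignment file as the denominator. Thresholds on
these percentages are plain mean ± 2 SD over windows holding at least one
read — empty windows would deflate the mean with unsequenced territory, so
they are reported with 0 % but excluded from fitting, and are never
flagged.

On "1000 base windows with 200 overlap": we read this as width 1000 with
step 800 (consecutive windows share 200 bp), the common make-windows
idiom; `pair_step` is a parameter if the other reading (step 200) is
wanted.

## Homozygous variants

Only homozygous **non-reference** genotypes are evidence (hom-reference is
everywhere and carries no signal). Each such site is expanded to 100 bases
before through 100 bases after its reference footprint — 201 bp for a SNV,
more for deletions, the footprint rather than the anchor base for indels —
clipped at chromosome ends and merged. Sites can come from a single-sample
VCF, or from the built-in consensus-style caller (`call_homozygous_sites()`:
base quality ≥ 13, mapping quality ≥ 2, depth ≥ 8, alternate fraction
≥ 0.9), which exists so the synthetic pipeline runs without an external
caller; it is not a reimplementation of a likelihood-based caller and is
not intended for production variant calling.

## Multimappers and LC attribution

Removing ambiguous reads (mapping quality 0, the usual aligner convention
for equal-best placements) before coverage analysis creates LC regions in
repetitive sequence. `multimap_windows()` flags windows where more than
50 % of all overlapping reads are multimapped, and `lc_attribution()`
reports how much LC territory those windows explain, plus the median
per-window read count genome-wide versus in unexplained LC windows.
Multimapper regions and LOW windows never enter LQ.

## The simulator

`run_simulation()` builds a sample genome (i.i.d. bases at a target GC,
optionally with regional GC set by a profile), plants non-overlapping
misassemblies, draws fragments (uniform starts, Normal(427, 80) lengths
truncated at twice the read length, 0.1 % per-base error), and **projects**
the pairs into assembly coordinates through the event map instead of
running an aligner. Projection is deterministic under the seed and
isolates detector behaviour from aligner heuristics; its costs are listed
under limitations.

Event kinds and their planted signatures (event names follow the
SV-calling convention of describing the sample relative to the reference):

* `collapsed_duplication` — the sample carries two copies, each diverged
  at the stated rate from the single assembly consensus copy. Reads from
  both copies pile onto the kept copy (≈2× coverage → HIGH); positions
  where the consensus differs from *both* sample copies give unanimous
  alternate pileups (homozygous calls), positions where only the second
  copy diverges give ~50 % pileups (heterozygous calls).
* `false_tandem_duplication` — the assembly duplicates a single-copy
  segment. Fragments wholly inside the segment are assigned at random
  between the two assembly copies with mapping quality 0 (mates kept
  together); junction-spanning fragments anchor to the nearer copy at
  quality 60. Confident coverage collapses (→ LC) and the windows are
  multimapper-dominated (→ MULTIMAP).
* `inversion` — the assembly carries the reverse complement. Pairs fully
  inside remain properly oriented (the mirrored pair is still FR); only
  junction-spanning pairs become improper, with one mate thrown to the
  opposite end of the inversion.
* `assembly_deletion` — the assembly carries a novel segment the sample
  lacks; spanning pairs stretch to ≈ insert + length (LARGE_INSERT).
* `assembly_insertion` — the sample carries a segment the assembly lacks;
  spanning pairs shrink to ≈ insert − length (SMALL_INSERT), and reads
  fully inside the absent sequence are dropped (counted). Reads partially
  inside anchor to the side holding the majority of their mappable bases,
  as an aligner would place them (soft-clipping itself is not modelled).
* `substitution_error` — consensus substitutions across a segment,
  homozygous-call signal only.

A projected pair is marked properly paired (SAM 0x2) iff both mates land
on one chromosome in leftmost-forward/rightmost-reverse orientation with
an outer template length within insert mean ± 4 SD, mimicking an
aligner's proper-pair window.

### Default scenario and why

One 500 kb chromosome, 40× fragment depth, 427 ± 80 bp inserts, 100 bp
reads, 0.1 % error, seed 42; one event per kind: 5 kb collapse
(divergence 1 %), 5 kb false tandem duplication, 4 kb inversion, and
300 bp deletion/insertion events. The indels are deliberately sized well
below the insert length: an indel much larger than the insert cannot be
spanned by any pair and therefore has *no* template-length signature —
300 bp against a 427 ± 80 bp library is the regime where insert-size
detection genuinely operates. These sizes keep a full simulate–detect
cycle under a minute on one CPU while giving every detector dozens to
hundreds of informative pairs; they are the problem sizes used throughout
the tests.

### Evaluation against truth

`evaluate_misassemblies()` scores each evidence track against the truth
intervals of the kind it should detect, by bases. For inversions the
target is the two breakpoint neighbourhoods (junction ± insert mean), not
the full inverted interval: pairs fully inside an inversion are properly
oriented, so no paired-end method can flag the interior of an inversion
longer than its insert size, and scoring the interior would measure the
window grid rather than the detector. The truth BED still records the
full interval. When a track flags nothing, precision is reported as 1
with the zero flagged-base count alongside.

## Numerical and edge-case choices

* Coordinates are 0-based half-open externally (BED) and 1-based closed
  internally (GRanges); constructors and writers convert.
* Merging fuses bookended intervals (distance 0), matching the default of
  the standard BED toolkit; gap-window removal uses any-overlap (≥ 1 bp).
* Histogram bin width for the robust fit is 1 coverage unit; the
  nonlinear least squares uses Levenberg–Marquardt with analytic-free
  restarts from the percentile moments and errors out (rather than
  silently degrading) if it cannot converge.
* Degenerate inputs error early: all-zero coverage medians, insert SD of
  0, fewer than 1000 usable pairs, fewer than 100 windows/values for any
  distribution fit.
* Windows at chromosome ends are truncated; a truncated window fully
  contained in its predecessor is dropped (it would re-count the same
  bases).
* The per-window read counts use any-overlap of the read span; counting
  by start position is the other defensible choice and changes
  denominators by ~10 % at these read lengths.

## What the synthetic results do and do not show

The simulator produces exactly the signatures the detectors target, with
uniform fragment sampling, perfect FR orientation, fixed read length, no
PCR duplicates, no base-quality structure, no soft-clipping, and
projection in place of alignment. Passing the planted-recovery tests
therefore demonstrates that the statistics, thresholds and interval
algebra do what they claim on data satisfying the model's assumptions. It
does **not** demonstrate robustness to aligner-specific artifacts
(clipping, mismapping between diverged repeats), to true heterozygous
structural variation, to coverage waves beyond the planted GC response,
or to chimeric library artifacts — on real data those effects widen the
fraction distributions and move every fitted threshold with them. The
2-SD design self-calibrates to whatever library it is given, which is the
method's main defence on real data.

## Worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 42)
sim <- run_simulation(cfg, default_misassemblies(), outdir = "sim")
res <- detect_regions(file.path("sim", "reads.sam"),
                      file.path("sim", "assembly.fa"),
                      gaps = file.path("sim", "gaps.bed"))
res
evaluate_misassemblies(res$tracks, sim$corr$truth, res$layout,
                       breakpoint_pad = cfg$insert_mean)
write_results(res, "out")
```

The README shows the numbers this prints and how to read them.
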