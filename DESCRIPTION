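Package: asmqc
Title: Low-Confidence Region Detection for Draft Genome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Flags low-quality (LQ) and low-coverage (LC) regions of a draft
    genome assembly from alignments of the reference individual's own
    paired-end reads. Windows with abnormal GC-normalized fragment coverage,
    elevated fractions of abnormally small or large insert sizes, depressed
    proper-pairing rates, proximity to homozygous non-reference variants, or
    multimapper dominance are detected, merged into LQ/LC/LQLC region tracks,
    and summarized against annotation sets. Includes a deterministic
    simulator that plants misassemblies (collapsed duplications, false
    tandem duplications, inversions, indels) into a synthetic genome and
    projects read-pair alignments into assembly coordinates so every
    detector can be validated end-to-end against truth intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    IRanges,
    S4Vectors,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation,
    data.table,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
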