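Package: knncnv
Title: Rare Copy-Number Variant Detection from Exome Read Depth with
    Per-Region Background Normalization
Version: 0.1.0
Authors@R: person("Maintainer", "knncnv", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects rare copy-number variants (CNVs) from whole-exome
    sequencing read depth. Instead of normalizing all capture regions of a
    chromosome in one run, every sequencing region is normalized
    independently together with its k most Pearson-correlated regions under
    a Poisson log-linear latent-factor model; the per-region results are
    joined into a normalized coverage matrix, segmented with circular binary
    segmentation, and converted into deletion/duplication calls with integer
    copy numbers. Includes depth-of-coverage computation from BAM files,
    the standard exome QC filters (GC, mappability, median depth, region
    length), alternative background-selection modes (random, GC, length,
    mean depth), a synthetic WES coverage generator with spiked CNVs, and a
    stratified evaluator (rare/common, short/long).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    parallel,
    Rsamtools,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
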