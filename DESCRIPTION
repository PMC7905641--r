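Package: mosaicscan
Title: Windowed Allelic-Imbalance Detection of Mosaic Copy Number Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects mosaic copy number variants (deletions, duplications and
    copy-neutral loss of heterozygosity) from SNP-array B-allele frequency
    (BAF) and log R ratio (LRR) signal files. Scans the genome in fixed 1-Mb
    windows, tallies BAF genotype bands, derives per-sample interquartile-range
    outlier thresholds on windowed BAF standard deviation and mean LRR, merges
    and refines candidate windows into events with probe-level breakpoints,
    and applies a filtering cascade (homozygous-deletion exclusion, minimum
    event size). Ships a signal simulator with a mixture model of mosaic BAF
    banding for benchmarking, and a majority-vote concordance module for
    comparing callers at the sample level.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
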