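Package: chipcompare
Title: Cross-Platform Comparison of ChIP-chip and ChIP-seq Signal Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing protein-DNA interaction profiles measured by
    tiling microarray (ChIP-chip) and high-throughput sequencing (ChIP-seq).
    Implements binned profile construction with Gaussian smoothing and
    log-ratio enrichment, input-DNA library quality control (GC-bias
    correlation, read subsampling, coverage saturation), signal-to-noise and
    reproducibility statistics, a platform-agnostic heuristic peak caller
    with Benjamini-Hochberg false discovery rate control, strand-aware
    average signal profiles around transcription start and end sites, and a
    synthetic-data generator that emulates both platforms from one shared
    underlying enrichment signal so every stage can be validated against
    planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    IRanges,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    e1071,
    withr,
    optparse,
    rtracklayer,
    GenomicRanges,
    S4Vectors
Config/testthat/edition: 3
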