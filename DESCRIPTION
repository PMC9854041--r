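Package: ecomethyl
Title: Ecotype-Comparative Seed Methylome and Small RNA Analysis
Version: 0.1.0
Authors@R: person("Maintainer", "Package", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Windowed whole-genome bisulfite sequencing methylation
    quantification with per-window validity criteria, partition of the
    genome into common and ecotype-specific regions from a six-sample
    validity matrix, calling of ecotype-differential methylated regions
    (eDMRs) by the mean plus/minus one standard deviation rule on
    per-window methylation differences, classification of 24-nt small RNA
    clusters by ecotype-wise differential expression, randomization-based
    interval permutation enrichment tests, and SNP/structural-variant/HOT
    region methylation summaries. Ships a two-ecotype, three-stage seed
    methylome simulator with a machine-readable truth table so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomeInfoDb,
    tools,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors,
    edgeR,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
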