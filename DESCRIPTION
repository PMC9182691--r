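Package: mirtarnet
Title: Network-Assisted Selection of miRNA Target Predictions and
    Binding-Site Feature Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects subsets of predicted microRNA binding sites that are
    over-represented among the target genes of a transcription factor, using
    a Monte-Carlo over-representation test with a site-density correction
    factor and Benjamini-Hochberg adjustment, and contrasts 3'-UTR
    binding-site features (UTR length, absolute and relative site position,
    windowed GC-content profiles around sites, multi-site multiplicity,
    inter-site distance and GC-content) between the selected subset and the
    background using a ratio-of-means resampling test and Fisher's exact
    tests. Reads TargetScan-7.2-style flat files and ships a synthetic-data
    generator with planted seed-match sites, configurable enrichment in a
    factor-bound gene set, GC gradients and GC dips around sites, so the
    whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
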