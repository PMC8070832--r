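Package: sexbiasmir
Title: Sex-Biased Genes and microRNAs in Anti-Correlated mRNA-miRNA Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Identifies sex-biased genes and microRNAs among the members of
    significant anti-correlated mRNA-miRNA clusters across cancer types,
    summarizes bias composition and tumor/normal fold-change distributions,
    aggregates multi-method tumor immune-infiltration correlations into
    per-gene correlation scores, selects inversely correlated pairs linking
    female-biased genes to X-linked cancer-related miRNAs, and tests whether
    the closest genomic neighbors of candidate genes share their differential
    expression direction. Ships a seeded synthetic-data generator with
    planted ground truth so every stage runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    stats,
    utils,
    methods,
    yaml,
    jsonlite,
    SummarizedExperiment,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
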