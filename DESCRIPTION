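Package: hyphachrom
Title: Chromosome Dynamics and Nucleoid-Associated Protein Binding in Streptomyces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative toolkit for studying how a nucleoid-associated protein
    (an HU homologue) and topoisomerase I shape chromosome organisation in
    filamentous bacteria. Implements single-molecule (PALM) track linking and
    two-state diffusion-mixture fitting with confined/free/mixed track
    classification; 1D fluorescent-focus detection along hyphae with
    tip-distance, inter-focus and focus-duplication metrics and
    germination/stall phenotype rules; a sliding-window differential
    ChIP-binding analysis (69/23 bp windows, local background filter,
    negative-binomial GLM, Simes-combined merged regions, AT-content scoring);
    and log-logistic growth-curve statistics. Every stage is paired with a
    synthetic-data generator with known ground truth so the full pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    mclust
Config/testthat/edition: 3
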