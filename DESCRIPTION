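Package: predimotif
Title: PRE Di-Motif Scanning and Kar4-Dependent Transcription Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis pipeline for dimeric pheromone response
    element (PRE) binding by the yeast transcription factor Ste12. Provides
    strand-aware enumeration and scanning of PRE di-motif configurations
    (head-to-head, head-to-tail, tail-to-tail; 0-100 nt spacing) with
    per-PRE mismatch accounting and an exact match-count significance model;
    ChIP-exo binding-region preparation, best-motif assignment and
    mismatch-spectrum summaries; peak-to-gene association with LTR flagging
    and RPM occupancy quantification; threshold-based classification of
    genes by Kar4 dependence from differential-expression tables; PSAM-based
    motif activity inference by multivariate regression of expression
    fold-changes on promoter affinities; hypergeometric enrichment,
    Benjamini-Hochberg correction and exact Mann-Whitney tests; and a seeded
    synthetic-data generator that emits every input the pipeline consumes
    together with a ground-truth table for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
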