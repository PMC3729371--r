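Package: structome
Title: Comparative Gene Structure, Splicing and Functional Annotation Analytics
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for comparative analysis of plant genome annotations:
    GFF3-backed gene models with derived UTRs and region-classified introns,
    per-genome gene-structure statistics and 5'-UTR intron profiling,
    pairwise classification of alternative-splicing events into the standard
    PASA-style taxonomy, gene-family size/orphan/expansion profiling and
    cluster-based inference of secondary intron loss, weighted majority-rule
    consensus of subcellular localization predictions into GO cellular
    component annotations (with GO-slim mapping and two-species term
    enrichment), and Wright's effective number of codons. Includes seeded
    synthetic-data generators that plant ground truth for every analysis
    stage, and a pipeline driver producing tabular and JSON summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    Biostrings,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
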