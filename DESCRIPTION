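Package: pgcmethylome
Title: Differential Methylome and Transcriptome Analysis of Primordial Germ Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing whole-genome bisulfite sequencing methylomes and
    RNA-seq transcriptomes of primordial germ cells (PGCs) and somatic cells across
    early zebrafish development. Implements per-CpG beta-binomial differential
    methylation testing, stitching of differentially methylated CpGs into regions
    with repeat, coverage and effect-size filters, a CpG-island (non-methylated
    island) promoter hypermethylation screen with Fisher exact testing and
    Benjamini-Hochberg correction, stage-wise differential expression with
    PGC-marker calling and clustering, and differential exon-inclusion rules on
    percent-spliced-in tables. A seeded synthetic-data generator plants known
    differentially methylated regions, 5mC-target promoters, marker genes and
    differential exons so that every stage of the pipeline can be validated
    against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
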