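Package: ggppschar
Title: Characterization of Geranylgeranyl Diphosphate Synthase Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Dry-lab characterization pipeline for fungal geranylgeranyl
    diphosphate synthase (GGPPS, crtE) genes. Infers exon/intron structure by
    spliced alignment of a cDNA against its genomic locus and audits splice
    junctions against the GT-AG rule; finds and translates the open reading
    frame; computes protein length, average molecular mass and Bjellqvist
    isoelectric point; detects the first and second aspartate-rich motifs
    (FARM/SARM), extracts the chain-length-determination (CLD) region and
    classifies the enzyme into GGPPS types I/II/III; and maps functionally
    annotated residues between homologs by global alignment. Ships a seeded
    synthetic-data generator that emits multi-exon genes and motif-bearing
    proteins with machine-readable ground truth so every stage is testable
    offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    optparse
Config/testthat/edition: 3
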