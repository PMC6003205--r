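Package: floramark
Title: Organ-Specific Microsatellite Marker Development and Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Develops simple sequence repeat (SSR) markers from assembled
    genome and transcriptome sequences and screens them in silico. Detects
    perfect microsatellite loci (2-6 bp motifs, five or more repeats),
    designs constraint-satisfying flanking primer pairs, enumerates all
    potential electronic-PCR amplicons under position-specific mismatch
    policies to discard non-unique pairs, cross-references retained pairs
    against transcript contigs to flag gene-targeted markers, and screens
    cross-species transferability. Includes k-mer genome-size estimation,
    assembly summary statistics, marker polymorphism analysis (PIC, overall
    gene diversity, Nei 1972 distance, UPGMA with Newick export) and seeded
    synthetic-fixture generators with machine-readable truth tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    methods,
    stats,
    utils
Suggests:
    ape,
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
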