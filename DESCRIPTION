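Package: orgedit
Title: C-to-U RNA Editing Analysis in Plant Organelle Genomes
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identification and characterisation of cytidine-to-uridine RNA
    editing in plant chloroplast and mitochondrial genomes. Calls editing
    sites from paired genomic-DNA/cDNA sequences or DNA/RNA pileup evidence,
    maps sites onto stranded (possibly spliced) gene models to derive codon
    position and amino-acid consequence, profiles flanking-base preference,
    quantifies per-site editing levels from chromatogram peak heights or
    read counts with Wilson confidence intervals, and predicts
    pentatricopeptide-repeat (PPR) editing-factor/target-site interactions
    by position-weight-matrix scanning with exact dynamic-programming
    p-values. Ships machine-readable catalogues of the validated editing
    sites of the tea plant (Camellia sinensis) and a seeded synthetic
    organelle-data generator used as the test bed for every component.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
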