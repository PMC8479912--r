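Package: nanobarcoder
Title: Specimen DNA Barcodes from Multiplexed Nanopore Amplicon Pools
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Turns a single FASTQ of noisy nanopore reads from a massively
    multiplexed COI amplicon pool into per-specimen, quality-controlled DNA
    barcodes. Reads are assigned to specimen bins by approximate matching of
    primers and 13-bp tags, and one barcode per bin is reconstructed by a
    three-phase frequency-threshold consensus procedure (by read length, by
    read similarity, and by comparison against already-accepted barcodes)
    with translation, length and ambiguity quality control. Includes a
    barcode-set comparison module (identical/compatible/incorrect), a
    rarefaction-by-arrival analysis, and a nanopore read simulator so the
    whole pipeline is testable without external data. Multiple sequence
    alignments are delegated to MAFFT.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: MAFFT (>= 7)
Config/testthat/edition: 3
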