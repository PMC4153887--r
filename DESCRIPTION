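Package: methacomp
Title: Comparative Genomics of Methanogenic Archaea
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative analysis of archaeal (methanogen)
    genomes: genome feature statistics (coding density, intergenic sizes,
    codon and stop-codon usage, rRNA gene organization), prediction of
    pyrrolysine-containing proteins via amber-codon readthrough fusion,
    replication-origin mapping by degenerate ORB motif scanning and pairing,
    de novo CRISPR direct-repeat/spacer array detection, best-hit orthology
    with three-way core-genome partitioning and outgroup screening, and
    phyletic-pattern classification of methanogenesis marker families.
    Includes a synthetic annotated-genome generator that plants
    truth-recorded instances of every signal the detectors target.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
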