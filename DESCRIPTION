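Package: genomescape
Title: Genome Landscape Analysis for Chromosome-Scale Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterising the large-scale landscape of
    chromosome-scale genome assemblies: assembly summary statistics (NX,
    gaps, completeness arithmetic), terminal telomere track detection,
    tandem-repeat monomer discovery and centromeric satellite array
    scanning, windowed repeat and gene density tracks, centromere calling
    from repeat arrays, LTR retrotransposon density, and Hi-C contact
    depression, tandem gene array calling and cross-assembly comparison,
    collinear synteny block chaining with syntenic depth, and expression
    atlas filters (FPKM, detectable and tissue-specific gene sets).
    Includes a synthetic genome simulator that plants telomeres,
    centromeric satellite arrays, pericentromeric LTR fields, tandem gene
    arrays, assembly-collapse and inversion derivatives, diverged ortholog
    genomes, distance-decay Hi-C contacts, and multi-tissue count
    matrices, together with a ground-truth ledger for end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
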