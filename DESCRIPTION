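Package: mitekit
Title: Detection, Classification and Evolutionary Dating of Miniature
    Inverted-Repeat Transposable Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for genome-wide characterization of
    miniature inverted-repeat transposable elements (MITEs). Detects
    structurally valid MITEs from terminal inverted repeats (TIRs >= 10 bp)
    and target site duplications (TSDs, 2-10 bp), clusters them into
    families with majority consensus sequences, classifies superfamilies
    from TIR/TSD signatures, places elements in genomic context (exon,
    intron, flanking and promoter regions, 1-Mb window densities), dates
    insertions by Kimura 2-parameter divergence from family consensus and
    LTR retrotransposons by Jukes-Cantor LTR-pair divergence, computes the
    tau tissue-specificity index from FPKM matrices, calls MITE-derived
    miRNAs by precursor overlap, and calls domestication-associated
    presence/absence across pan-genome accessions. Ships a synthetic-genome
    simulator with complete ground truth so every stage is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    Rcpp,
    rtracklayer,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
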