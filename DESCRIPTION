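Package: ski7tools
Title: Isoform Architecture and Splice-Fate Analysis for HBS1/SKI7 Loci
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the alternatively spliced HBS1/SKI7 loci of
    land plants and other eukaryotes. Compiles degenerate consensus motifs
    (SKI7-like and Patch 4-like) into position-wise patterns and scans
    proteins against them; annotates the five-region HBS1/SKI7 protein
    architecture (acidic N-terminus, RanBP2-type zinc finger, SKI7-like
    motif, Patch 4-like motif, translational GTPase) and assigns isoform
    classes; detects alternative-splicing events (cassette exon, retained
    intron, alternative acceptor/donor) between transcripts of a gene;
    applies a premature-termination-codon rule to flag transcripts that are
    targets of nonsense-mediated decay; derives degenerate consensus strings
    and sequence-logo count matrices from protein alignments; and generates
    synthetic genomes, gene models and protein sets with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
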