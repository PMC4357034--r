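Package: htrscan
Title: Identification, Classification and Evolutionary Analysis of Histone H3 Variant Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide surveys of histone three
    related (HTR) genes. Scans an annotated proteome for H3 homologs by
    iterative local alignment, applies redundancy/isoform/incompleteness
    filters, maps candidate residues onto canonical mature-H3 numbering,
    and classifies candidates into CenH3, H3.1, H3.3, H3.1A and H3-like
    using signature residues at positions 31/41/87/90 together with
    intron evidence and CenH3 clade/tail evidence. Quantifies purifying
    selection with Nei-Gojobori (1986) dN/dS counting and a SLAC-style
    per-site selection test on parsimony-reconstructed ancestral codons,
    builds neighbor-joining phylogenies with bootstrap supports, and
    clusters developmental expression profiles. Ships a synthetic-data
    generator producing labelled genomes, codon alignments evolved at a
    known dN/dS, and expression matrices with planted archetypes, so the
    whole pipeline is testable against known truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
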