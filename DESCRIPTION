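Package: mitorecomb
Title: Repeat-Mediated Recombination Analysis for Plant Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the fluid structure of plant mitochondrial
    genomes. Identifies repeated sequence pairs in a genome and classifies
    them by size, builds master and alternative conformation references for
    each repeat pair, counts long reads supporting each conformation to
    detect ongoing repeat-mediated homologous recombination, computes
    double-cut-and-join (DCJ) rearrangement distances and conserved gene
    clusters from signed gene orders, annotates plastid-derived and shared
    homologous segments in intergenic spacers, and summarises concatenated
    alignment matrices (missing data, parsimony-informative sites). A
    seeded synthetic-data generator produces genomes with planted repeats,
    recombinant conformations, and long reads drawn from weighted
    conformation mixtures with full ground truth, so the whole pipeline can
    be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    tibble,
    dplyr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
SystemRequirements: NCBI BLAST+ (makeblastdb, blastn) on the PATH
Config/testthat/edition: 3
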