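Package: erosim
Title: Pseudogene Classification and Genome-Erosion Simulation for Bacterial Endosymbionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of genome degeneration in recently derived
    bacterial endosymbionts. Classifies orthologs of an ancestral (free-living)
    reference as intact, pseudogenized or absent from pairwise nucleotide
    alignments, tabulates the allelic spectrum of disrupting mutations
    (frameshifting indels, terminal truncations, nonsense substitutions and
    insertion-sequence acquisitions), computes base-composition and divergence
    metrics at second-codon, fourfold-degenerate and intergenic sites, and
    estimates the number of genes evolving under relaxed selection (visible
    plus cryptic pseudogenes) with a Monte Carlo simulation of length-biased
    mutation accumulation. A truth-labelled forward simulator of genome
    erosion makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
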