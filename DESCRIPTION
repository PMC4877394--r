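Package: cpevol
Title: Comparative Structural Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analyses of chloroplast (plastid) genome
    architecture in green algae and land plants: detection of the large
    inverted repeat and the quadripartite IR/SSC/LSC structure, signed
    gene-order extraction, signed gene-pair (adjacency) matrices, pairwise
    synteny blocks, exact signed reversal distances via the
    Hannenhalli-Pevzner breakpoint graph, distance-based branch-length
    fitting on a fixed phylogeny, Dollo (and Fitch/Wagner) parsimony mapping
    of gene, intron, gene-pair and IR characters, nucleotide-composition and
    small-repeat statistics, colinear-genome divergence, and a tRNA decoding
    audit. A seeded simulator of chloroplast genome evolution along a rooted
    tree provides annotated genomes with logged ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    pracma,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
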