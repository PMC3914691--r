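Package: grasskaryo
Title: Paleopolyploidy, Biased Fractionation and Ancestral Karyotype
    Reconstruction in Grass Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A paleogenomics inference chain for diploidized paleopolyploid
    genomes, built around the grass whole-genome duplication (WGD) shared
    50-70 million years ago. Implements cumulative identity/alignment-length
    (CIP/CALP) homology filtering, Ks-based dating of duplication events with
    log-normal mixture modelling and BIC model selection, collinear synteny
    block chaining, classification of WGD-derived gene pairs into retained
    and shuffled duplicates, chi-square tests of dominant versus sensitive
    subgenome compartments, contiguous ancestral region (CAR) reconstruction
    by conserved-adjacency voting, and a rule-based engine that evaluates
    candidate ancestral karyotype scenarios under subgenome-dominance and
    centromere-functionality constraints. A forward simulator of grass-like
    genome evolution (WGD, biased gene deletion, transposition, inversion,
    tandem duplication, segmental deletion, chromosome fusion/fission)
    provides ground-truthed inputs so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
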