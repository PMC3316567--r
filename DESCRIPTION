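Package: selevo
Title: Evolution of Vertebrate Selenoproteomes: Event Reconstruction,
    SECIS Scanning, Gene Features and Phylogenetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying the composition and evolution of vertebrate
    selenoproteomes. Reconstructs gene birth, loss and selenocysteine-to-
    cysteine conversion events on a rooted species tree from a phyletic state
    matrix (Dollo presence reconstruction plus Sankoff parsimony with an
    irreversibility constraint), ships a curated vertebrate phyletic fixture,
    scans nucleotide sequence for SECIS elements with an explicit structural
    grammar, computes selenoprotein gene geometry (UTR lengths, UGA-to-SECIS
    distances, stop-codon readthrough, pseudogene lesions), estimates Ka/Ks by
    the Nei-Gojobori method with Jukes-Cantor correction, and implements a
    model-selection phylogenetic workflow (BioNJ starting tree, likelihood
    under seven empirical amino-acid models, AIC ranking, NNI search and aLRT
    branch support). Includes seeded simulators for genomes with planted
    selenoprotein genes, codon evolution at a fixed dN/dS, pseudogenization
    lesions, and amino-acid alignments evolved on a tree.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
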