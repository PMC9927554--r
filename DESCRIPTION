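Package: ervfossils
Title: Detection and Reconstruction of Retroviral Protein Fossils in Genomic DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for discovering protein fossils: genomic DNA segments
    descended from formerly protein-coding sequence, typically inside decayed
    endogenous retroviruses (ERVs).  Provides training of a 64x21 codon-versus-
    amino-acid log-odds substitution matrix from diverged DNA/protein pairs,
    frameshift-tolerant local DNA-versus-protein alignment with simple-repeat
    masking and empirical score calibration, genome-wide scanning with
    RepeatMasker annotation overlap analysis and consensus-coordinate
    projection, Refiner-style iterative ancestral consensus reconstruction with
    open reading frame discovery, and neighbor-joining phylogenetics with
    Jukes-Cantor distances and bootstrap support.  A seeded simulator of ERV
    proliferation and decay supplies ground-truth test data for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    stats,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
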