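Package: pepsim
Title: Chemical Similarity Analysis of Phage-Display Peptide Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies chemical diversity and dissimilarity between families
    of phage-display-selected peptides. Converts one-letter peptide sequences
    into SMILES-based molecular graphs, computes MinHashed atom-pair
    fingerprints with an exact-Jaccard brute-force oracle, and compares
    panels by whole-sequence Jaccard similarity, per-position Jaccard
    similarity, and TF-IDF cosine similarity of the residue text. Includes
    motif scanning (HPQ/HPM, CPXN-type consensus), position-frequency and
    information-content (sequence logo) analytics, and a seeded synthetic
    panel generator emulating CX10C phage-display libraries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    generics,
    withr,
    igraph,
    Biostrings,
    ChemmineR,
    ChemmineOB,
    optparse,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
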