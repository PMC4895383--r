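Package: ubimotif
Title: Ubiquitylation Site Prediction from Substrate Motifs with Two-Layered SVMs
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Predicts ubiquitin-conjugation (ubiquitylation) sites on lysine
    residues from protein sequence. Extracts fixed-width peptide windows
    centred on candidate lysines, encodes them with a family of sequence and
    structure feature representations (one-hot, amino-acid and dipeptide
    composition, position weight matrix, position-specific scoring matrix
    profiles, solvent accessibility and secondary structure), discovers
    substrate motif subgroups by recursive maximal-dependence decomposition
    (chi-square partitioning), and fuses per-motif radial-basis SVM
    probability estimates in a second-layer SVM. Includes greedy
    identity-based homology reduction, stratified cross-validation with
    confusion-matrix metrics, position-specific residue enrichment analysis,
    a synthetic proteome generator with planted motifs for end-to-end
    testing, and a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
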