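Package: plastidclass
Title: Two-Phase SVM Classification of Plastid Proteins from Sequence Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies plastid proteins and classifies them into functional
    plastid types (chloroplast, chromoplast, etioplast, amyloplast) using
    radial-basis-function support vector machines trained on five
    sequence-derived feature encodings: amino-acid composition, dipeptide
    composition, pseudo amino-acid composition, terminal-segment (N/Center/C)
    composition, and physicochemical property classes including the
    theoretical isoelectric point. Provides the full surrounding workflow:
    FASTA input with sequence sanitization, homology reduction to a pairwise
    identity cutoff, stratified cross-validation, decision-threshold scans,
    ROC/AUC and confusion-matrix metrics, a synthetic labeled-sequence
    generator for benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
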