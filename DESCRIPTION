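Package: rbpbindr
Title: Prediction of Protein-Binding Regions in RNA from Nucleotide
    Profiles and Compositions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts protein-binding regions in mRNA sequences with a
    support vector machine over position-specific log-odds profiles of
    mono- and di-nucleotides, k-mer compositions, and optional
    composition/transition/distribution (CTD) descriptors of the binding
    protein.  Includes dataset construction from genomic region tables
    (length/affinity/strand filtering, random and upstream negative
    sampling, greedy redundancy removal, class-ratio datasets, stratified
    splits), a synthetic motif-planted sequence generator with known
    ground truth, 10-fold and leave-one-protein-out cross-validation with
    pooled confusion counts, ROC/AUC construction, and a command-line
    interface for reproducible runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    e1071,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
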