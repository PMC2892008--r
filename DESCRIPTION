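Package: gpsno
Title: Group-Based Prediction of Protein S-Nitrosylation Sites
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains and applies group-based peptide-scoring predictors of
    protein S-nitrosylation (SNO) cysteine sites in the style of the GPS 3.0
    algorithm. Cysteine-centred peptides are scored against experimentally
    verified reference sites with a BLOSUM62-derived substitution matrix; the
    trainer partitions the reference sites by similarity k-medoid clustering,
    selects a flanking-window size per cluster, hill-climbs per-position
    weights and matrix entries against leave-one-out sensitivity at fixed
    specificity, and calibrates high/medium/low score cutoffs. Position-
    specific scoring matrix (PSSM) and acid-base motif baselines, a full
    evaluation protocol (leave-one-out, k-fold cross-validation, ROC/AROC),
    a deterministic planted-signal sequence simulator, and a command-line
    interface are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
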