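Package: mirtarget
Title: Two-Level Prediction of miRNA Target Sites and Target Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts animal miRNA targets at two levels. Candidate target
    sites on a 3' UTR are located by a seed-weighted complementarity
    alignment; each site is described by 151 features covering duplex
    energetics, seed-match taxonomy, per-position pairing, target-site
    accessibility, nucleotide composition, conservation and location, and
    each miRNA-gene pair by 624 summary features. Negative training
    examples come from seed-disjoint shuffled (mock) miRNAs. Includes
    mutual-information feature selection (CFS with best-first search and
    mRMR ranking), six posterior-emitting classifiers, cross-validation
    and hold-out evaluation, and an overlap-threshold ROC protocol for
    site-level benchmarking, plus a synthetic-data generator so the whole
    pipeline runs self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    MASS,
    e1071,
    randomForest,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
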