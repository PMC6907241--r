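Package: nucleolearn
Title: Dynamic Reference Learning for Low-Coverage Amplicon Assembly
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reference-guided assembly of short sequencing reads by online
    learning. Reads are encoded as per-base nucleotide probability vectors
    (a probabilistic Voss representation built from Phred qualities) and
    aligned one at a time to an evolving reference by free-ends dynamic
    programming. After each alignment the reference is pulled toward the
    read population: substitutions by convex averaging of probability
    vectors under an edit-rate-dependent learning-rate schedule, and
    insertions/deletions through a per-position persistence vector that
    triggers structural edits once enough concordant evidence accumulates.
    Includes the calibration simulator used to set the learning-rate
    schedule, a read/reference mutation simulator, and an assembly
    evaluator based on global affine-gap alignment with the NUC.4.4
    scoring matrix and free end gaps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    S4Vectors,
    tibble,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    withr,
    optparse
Config/testthat/edition: 3
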