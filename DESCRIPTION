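Package: embalign
Title: Embedding-Based Alignment and Nearest-Bait Classification of
    Protein Superfamilies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pairwise global alignment of proteins in the space of
    per-residue protein language model embeddings, and its use for
    superfamily class assignment by annotation transfer. Residue-pair
    Euclidean distances between two per-residue embedding matrices are
    background-normalised ("signal enhancement") into a position-specific
    substitution matrix, aligned with an affine-gap Needleman-Wunsch
    dynamic program, and scored with the length-normalised EBAmin
    statistic. Queries take the class of their best-scoring reference
    ("bait") and are triaged against per-class reference length ranges as
    a proxy for fold conservation. Ships a curated metadata fixture for
    the 20-class Glutathione S-transferase (GST) reference set, a
    class-structured synthetic data generator for end-to-end benchmarking
    without external downloads, redundancy filtering of query sets
    against the reference, and the aggregation arithmetic for
    labeled-agreement and length-region summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
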