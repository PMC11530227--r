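Package: protannot
Title: Fast Functional Annotation of Transcriptome Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained transcriptome functional-annotation pipeline.
    Translated transcript (or long-read) sequences are optionally collapsed by
    linear-time greedy redundancy clustering, then searched with an internal
    homology engine (k-mer prefilter plus affine-gap local alignment, and
    position-specific scoring matrix scans of profile databases) against one
    protein sequence database and any number of profile databases.  Hits are
    filtered by E-value, reduced by best-hit (sequence targets) and
    non-overlapping tiling (profile targets) policies, and target annotations
    (descriptions, GO terms, orthogroups, domain names) are transferred to the
    queries and written as a merged tab-separated table with an
    annotation-rate summary.  Includes generators for synthetic reference
    databases and query sets with planted ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
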