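Package: opsimatch
Title: Exact and Mismatch-Tolerant Pattern Matching for Biological Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Exact and substitution-tolerant (k-mismatch) pattern search in DNA
    and protein sequences built around a KMP-style failure table (the longest
    proper prefix that is also a suffix). Provides the failure-table
    construction, a linear-scan exact matcher, an approximate matcher that
    tolerates up to a fixed number of substitutions per occurrence with
    failure-table restarts anchored at the first mismatch of the current
    alignment, and baseline matchers (naive scan, pattern automaton,
    Boyer-Moore bad-character preprocessing, sliding-window hamming search).
    Includes a seeded synthetic-sequence generator with planted mutated
    occurrences, a hardware-independent benchmark harness instrumented by
    character-comparison counts, FASTA input, TSV/BED output and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
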