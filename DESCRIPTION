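Package: fpsearch
Title: Fast Similarity Search for Binary Molecular Fingerprints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Read, write, and search dense binary molecular fingerprints.
    Implements the line-oriented FPS text format and a chunked FPB binary
    format, a contiguous popcount-sorted fingerprint arena, and
    BitBound-pruned Tanimoto and Tversky similarity search (threshold,
    k-nearest, multiquery, and symmetric N-by-N modes), with all
    accept/reject decisions made in exact integer arithmetic.  Includes
    streaming FPS file-scan search, command-line tools for searching,
    converting, and extracting fingerprints from SD files, a synthetic
    fingerprint generator, and an instrumented benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    optparse,
    parallel,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
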