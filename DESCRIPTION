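Package: repindex
Title: Compressed Document-Retrieval Indexes for Repetitive String Collections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Index structures and query algorithms for document retrieval on
    repetitive string collections such as pan-genome sequence databases and
    versioned document archives. Implements document listing and counting over
    a run-length encoded interleaved LCP array, precomputed document lists on a
    sampled suffix tree with Re-Pair grammar compression of the stored sets
    (including top-k retrieval with frequency-sorted lists), Sadakane-style
    constant-time document counting with compressed encodings and filters, and
    ranked multi-term tf-idf queries built on incremental top-k extraction.
    Includes brute-force oracles for verification and generators of synthetic
    repetitive collections (duplicated sequences with entropy-preserving point
    mutations) together with pattern extraction utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
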