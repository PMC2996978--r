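Package: ranksets
Title: Exhaustive Rank-Based Enumeration of Partition-Inducing Gene Sets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A direct alternative to two-way hierarchical clustering of
    expression matrices. Each gene is reduced to the set of its top-s
    highest-expression samples; two genes belong to the same gene set when
    their top-s sample sets agree up to a tolerance t. Scanning a grid over
    (s, t) enumerates every partition-inducing gene set in the matrix as a
    connected component of the match graph, instances of the same set across
    grid cells are consolidated ("squashed") into core sets, and each core
    set is evaluated against survival outcomes by log-rank tests on median
    and quartile splits of its column-sum score, optionally stratified by
    estrogen-receptor status. Includes readers for tab-delimited and
    series-matrix expression dialects, k-nearest-neighbour imputation, and a
    seeded synthetic-data generator with planted biclusters and survival
    structure for benchmarking recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    survival,
    jsonlite,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
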