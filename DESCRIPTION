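Package: panmem
Title: Pangenome Indexing with Maximal Exact Match Overlaps for
    Arbitrary-Length k-mer Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds compact pangenome indexes from maximal exact matches
    (MEMs) between a designated pivot genome and every other genome in a
    collection, and answers k-mer membership and conservation queries over
    pivot coordinates for any k-mer length from a single index. Matching
    statistics are computed exactly with a suffix automaton over each
    target genome and its reverse complement; MEMs correspond to peaks of
    the matching-statistics landscape, and only the overlaps between
    consecutive MEMs are stored. Column-sorting the matching-statistics
    matrix yields order-MEMs, which support conservation counts with
    early stopping, quantile (e.g. decile) subsampling for lossy smaller
    indexes, and interval-length filtering that losslessly restricts the
    supported k-mer range. Indexes are stored as ZSTD-compressed Parquet
    tables with region reads driven by columnar predicate pushdown.
    Includes a seeded synthetic-pangenome simulator and brute-force
    oracles so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    arrow,
    Biostrings,
    dplyr,
    jsonlite,
    Rcpp,
    grDevices,
    graphics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
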