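Package: booldp
Title: Determinative Power and Minimal Determinative Subnetworks of Boolean
    Network Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact information-theoretic node ranking for logical (Boolean)
    models of biological networks. Computes the mutual information between each
    update rule and each of its inputs directly from truth-table supports under
    an independent input distribution, sums these information gains into each
    node's determinative power (DP), and selects a minimal "most determinative"
    subnetwork by thresholding a moving average of the consecutive decrements
    of the conditional-entropy upper bound curve. Also provides the wiring
    digraph's degree, closeness and betweenness attributes, per-network cohort
    summaries with regression fits, top-k essential-node enrichment, parsers
    and writers for logic-expression files and per-node truth-table
    directories, and a seeded random-network generator with brute-force
    enumeration oracles for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
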