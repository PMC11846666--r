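Package: netcontext
Title: Contextualization and Benchmarking of Signed Directed Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained toolkit for context-specific subnetwork inference
    on signed directed prior-knowledge networks (PKNs). Provides a PKN graph
    data model with SIF, edge-list TSV and GraphML input/output; eight network
    contextualization methods spanning four families (topology-based path
    search, diffusion via personalized PageRank and truncated heat kernels,
    recursive upstream propagation, and causal sign-consistency selection);
    four evaluation strategies with size-matched permutation nulls; and a
    synthetic-fixture generator with planted, sign-consistent source-to-target
    paths so that every method and benchmark is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
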