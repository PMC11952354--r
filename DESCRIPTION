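Package: kghop
Title: In-Memory Engine for Serving Biomedical Knowledge Graphs with
    One-Hop Semantic Queries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Loads Biolink-style biomedical knowledge graphs from KGX flat
    files (TSV or JSON Lines), builds an in-memory nested adjacency index,
    and answers one-hop graph pattern-matching queries with built-in
    semantic reasoning: category and predicate hierarchy expansion,
    predicate symmetry and canonical-direction handling, concept
    equivalence resolution, and transitive subclass chaining. Also
    derives a meta knowledge graph with exemplar test triples, persists
    and restores indexes, and exposes hosted graphs through a TRAPI-style
    request router that supports multiplexing several graphs at separate
    endpoints. Ships a synthetic knowledge-graph generator and an
    index-free brute-force query oracle used to validate the engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    httpuv,
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
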