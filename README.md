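# kghop

An in-memory engine for serving Biolink-style biomedical knowledge graphs
with one-hop semantic queries.

Biomedical knowledge graphs are usually distributed as flat files — a nodes
table and an edges table in KGX format (TSV or JSON Lines) — but consumed
through standardized web APIs that must do real semantic work: a question
like *"what interacts with acetaminophen?"* should be answered not only
from edges asserted exactly that way, but also through category and
predicate hierarchies, predicate symmetry and canonical direction,
concept-identifier equivalence, and transitive subclass relations. `kghop`
is for knowledge-graph owners and tool builders who want to go from KGX
flat files to a queryable, reasoning-aware endpoint without standing up a
database server: everything lives in memory, all reasoning is precomputed
into indexes at build time, and query answering reduces to constant-time
dictionary lookups.

## The model

A **one-hop query graph** is two query nodes joined by one query edge,

```
qnode n0 [ids? categories?] --qedge e0 [predicates? constraints?]--> qnode n1 [ids? categories?]
```

at least one side pinned by identifiers. The engine returns *all* knowledge
subgraphs `(s, p, o)` that satisfy the pattern under five reasoning
behaviors:

1. **Hierarchies** — a query category or predicate matches all of its
   schema descendants (`treats` answers an `affects` query).
2. **Symmetry** — a symmetric predicate (`interacts_with`) matches in
   either orientation; a symmetric *query* predicate (including the
   predicate root `related_to`) is direction-free.
3. **Canonicity** — of an inverse pair (`treats`/`treated_by`) one
   direction is canonical; edges are stored in canonical orientation at
   build time, so a `treated_by` query and the equivalent `treats` query
   return the same edges.
4. **Concept equivalence** — queried CURIEs are resolved through
   equivalence clusters (union–find over `equivalent_identifiers`
   evidence), so an alias finds the edges of its cluster.
5. **Subclass chaining** — pinned concepts expand to all transitive
   `subclass_of` descendants, so a query about a disease also returns
   knowledge about its subtypes.

The core data structure is a nested adjacency dictionary:
`node → direction → neighbor category → canonical predicate → {edge ids}`,
paired with precomputed hierarchy closures so each reasoning behavior costs
a set union, not a traversal. A brute-force, index-free oracle
(`brute_force_answer()`) implements the same semantics by linear scan and
is used to validate the engine on thousands of randomized graphs.

## Worked example

The package ships a small demo graph (8 nodes, 8 edges, including an
inverse-asserted `treated_by` edge and a headache subclass chain) plus a
demo schema:

```r
library(kghop)
engine <- build_engine(system.file("extdata", "demo_kg", "config.json", package = "kghop"))
engine
#> <kg_engine> 'demo': 8 nodes, 8 edges
engine$index$stats$n_edges_flipped
#> [1] 1      # the treated_by edge, stored flipped as canonical `treats`

qg <- list(
  nodes = list(n0 = list(ids = "CHEBI:46195"), n1 = list(categories = "Protein")),
  edges = list(e0 = list(subject = "n0", object = "n1", predicates = "interacts_with"))
)
ans <- engine_answer(engine, qg)
ans
#> <kg_answers> 2 results, 3 knowledge nodes, 2 knowledge edges
answer_edge_ids(ans)
#> [1] "T001" "T002"
```

Acetaminophen (CHEBI:46195) interacts with both PTGS1 and PTGS2 — edges
T001 and T002. Subclass chaining and canonicity combine in a treatment
query pinned at the apex disease:

```r
qg2 <- list(
  nodes = list(n0 = list(categories = "ChemicalEntity"), n1 = list(ids = "MONDO:0002048")),
  edges = list(e0 = list(subject = "n0", object = "n1", predicates = "treats"))
)
for (r in engine_answer(engine, qg2)$results)
  cat(r$node_bindings$n0[[1]]$id, "->", r$node_bindings$n1[[1]]$id, "\n")
#> CHEBI:15365 -> MONDO:0005277    # aspirin treats migraine — matched via the
#>                                 # subclass chain (binding carries query_id
#>                                 # MONDO:0002048) and via a treated_by assertion
#> CHEBI:46195 -> MONDO:0002048    # acetaminophen treats headache disorder, direct
```

The meta knowledge graph summarizes what the graph can answer, with one
exemplar test triple per meta-edge:

```r
engine$metakg$meta_edges
#>    subject_category       predicate object_category count
#> 1:          Disease     subclass_of         Disease     2
#> 2:             Drug  interacts_with         Protein     3
#> 3:             Drug          treats         Disease     2
#> 4:             Gene associated_with         Disease     1
```

Serving over HTTP (several graphs can be multiplexed at separate
sub-endpoints; all query-time state is immutable, so concurrent readers
need no coordination):

```r
svc <- kg_service(engine)
route(svc, "GET", "/demo/meta_knowledge_graph")$status   # 200
# serve(svc, port = 8080)  # blocking HTTP server via httpuv
```

or from a shell, via the bundled CLI:

```sh
Rscript exec/kghop build --config inst/extdata/demo_kg/config.json --out demo.snapshot
Rscript exec/kghop query --config inst/extdata/demo_kg/config.json --query query.json
Rscript exec/kghop serve --config inst/extdata/demo_kg/config.json --port 8080
```

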