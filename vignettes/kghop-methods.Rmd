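---
title: "kghop methods: reasoning model, indexes, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{kghop methods: reasoning model, indexes, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kghop` turns a Biolink-style knowledge graph, shipped as KGX flat files,
into an in-memory one-hop query engine with built-in semantic reasoning.
This vignette explains the model the package implements, the data
structures that make queries constant-time, and the design decisions taken
where more than one reasonable choice existed.

## The semantic layer

The engine reasons over a *schema*: two rooted DAGs — node categories and
edge predicates — with per-predicate metadata (`symmetric`, `canonical`,
`inverse`). The schema is a small YAML/JSON document rather than a full
Biolink Model release: the same semantics with no network dependency, and
a converter from the real model can be layered on later. Multiple parents
are allowed because Biolink mixins create multi-parent elements. Labels
are case-sensitive after stripping an optional `biolink:` prefix at parse
time, which keeps matching deterministic across KGX dialects.

Reflexive ancestor/descendant closures for every label are precomputed at
`load_schema()` time into label-to-set maps. This is what turns hierarchy
reasoning at query time into a set lookup: the cost is paid once per
schema, not per query.

Schema validation is strict where the reasoning depends on it: both
hierarchies must be singly rooted and acyclic (Kahn's algorithm, reporting
a cycle member); an inverse declaration must be reciprocal, with exactly
one canonical member per pair; a symmetric predicate may not declare an
inverse (it is its own inverse). Unknown fields are ignored with a logged
warning so schema documents can carry extra annotations.

## The adjacency index

The core structure is a nested adjacency dictionary:

```
node id -> direction (out|in) -> neighbor most-specific category
        -> canonical predicate -> {edge ids}
```

Build-time normalization does most of the reasoning work:

* **Canonical orientation.** Every edge's predicate is rewritten through
  `canonical_form()`; an edge asserted via the non-canonical inverse
  (`X treated_by Y`) is stored flipped (`Y treats X`) with a `flipped`
  flag preserving its asserted orientation. Queries phrased either way
  then hit the same posting sets.
* **Symmetry.** Symmetric-predicate edges are posted under both endpoints
  in both directions, so they are reachable from either side without
  query-time special-casing.
* **Most-specific categories as keys.** A node labeled
  `[ChemicalEntity, Drug]` is indexed under `Drug` only; the full list
  stays on the node record. Edges are indexed under their asserted
  (canonicalized) predicate and most-specific categories *only*, and the
  query layer expands query labels to descendant sets before lookup. The
  alternative — indexing every edge under all ancestor labels — buys
  nothing asymptotically (posting-set unions over precomputed closures are
  already constant-time per key) and multiplies memory by the hierarchy
  depth; in an engine whose main cost is residency, the closure-on-query
  side of the trade is the right one.
* **Degenerate inputs.** Nodes with no schema-known category get the
  category root (warned, counted), so every node stays queryable. Edges
  referencing missing nodes are skipped and counted; edges with predicates
  unknown to the schema are treated the same way, since without schema
  metadata neither canonicity nor hierarchy placement is defined for them.
  All counts are exposed in `index$stats`.

After build the index is immutable; any number of concurrent readers may
query it with no coordination. Persistence (`save_index()`/`load_index()`)
is a versioned single-file snapshot whose only contract is faithful
restore — `load(save(x))` reproduces identical lookups for every key.

## Query semantics

`answer_query()` runs a fixed pipeline: validate and normalize the query;
expand pinned ids; expand categories and predicates through the schema;
collect candidate edges by index lookup from the pinned side with fewer
concrete ids; filter by the other side's constraints and by attribute
constraints; assemble deterministic results (sorted by subject id, object
id, with edge ids sorted within bindings; one result per concrete node
pair, all parallel edges bound to the single query edge).

Three semantic decisions deserve explicit statement:

* **Pinned-id expansion is reflexive.** A queried id expands to the union
  of its own subclass descendants and those of its equivalence-cluster
  representative. Expanding *only* through the representative would be
  marginally simpler, but on a graph that has not been canonicalized it
  would make a query for a non-representative cluster member lose that
  member's own edges — a direct match must never be lost to equivalence
  redirection, and the meta-KG's test triples (which re-query concrete
  stored edges) rely on that reflexivity.
* **`ids` and `categories` on the same query node combine conjunctively**,
  matching general TRAPI practice: both constraints must hold.
* **Symmetric query predicates are direction-free.** A query edge whose
  predicate is symmetric — or is the predicate root, which expresses no
  type constraint at all — matches edges under all of its descendant
  predicates in either orientation. This is what makes a `related_to`
  query return *every* edge incident to the pinned node, even those
  asserted with a directional, non-invertible predicate like `affects`
  pointing at the pinned node. Directional query predicates keep their
  direction. Only descendant expansion is applied to query categories;
  nodes labeled only with general categories do not match more specific
  query categories (ancestor matching is not implied by the hierarchy
  semantics and would make category constraints non-monotone).

Attribute constraints follow any-value/all-constraint semantics: a
constraint passes if any value of the (possibly list-valued) property
satisfies the operator; an edge passes if all constraints pass; `negated`
inverts a single constraint; a missing property fails a plain constraint
and passes a negated one. Comparisons are numeric when both sides parse as
numbers, lexicographic otherwise; `matches` is a regular-expression
search. Responses report knowledge edges in stored (canonical)
orientation; node bindings follow the query orientation and carry a
`query_id` whenever the matched id differs from the queried one.

## Canonicalization

Concept equivalence is a union–find over `(node id, equivalent id)` pairs,
so shared identifiers chain transitively. The cluster representative is
the lexicographically smallest member that is an actual graph node id
(falling back to the smallest member), optionally biased by a
prefix-priority list; any deterministic rule works, and this one is easy
to reason about in tests. Merging keeps the representative's id and name,
unions categories and equivalent identifiers, remaps and deduplicates
edges on `(subject, predicate, object, primary knowledge source)` with
list-union of properties, drops edges made self-referential purely by the
merge, and records every removal in attached statistics so the edge
multiset is conserved up to logged counts. Scalar property conflicts keep
the representative's value and preserve the losers under a
`merged_values` record — lossless and deterministic. The operation is
idempotent: re-running it (with an equivalence map rebuilt from its own
output) changes nothing.

The live Translator Node Normalizer web service is deliberately not
called; the provider abstraction accepts the in-file
`equivalent_identifiers` evidence, an external member/representative TSV,
or a user-supplied function, so builds are reproducible offline.

## Subclass closure

Concept subclass chaining uses the graph's own `subclass_of`-style edges
(the predicate list is configurable) plus optional external pair files.
Chaining depth is unlimited by default with a visited-set guard: no depth
cap is obviously principled, and the guard makes cycles terminate with
members becoming mutual descendants (reported with a warning). A
`max_depth` knob exists for graphs where deep ontology chains are
unwanted.

## The synthetic generator and what passing tests mean

`fixture_spec()`/`generate_kg()` produce randomized KGX graphs with
*planted, manifest-recorded* semantic structure: multi-member equivalence
clusters (via shared alias identifiers), disease subclass chains whose
members each carry a marker treatment edge, a controlled fraction of
symmetric and of inverse-asserted edges, multi-category nodes, and edge
properties (knowledge source, publications, a numeric-valued score)
usable by attribute constraints. Defaults (120 nodes, 400 random edges,
20% symmetric, 25% inverse-asserted, 4 clusters, chains of 3 and 4, 15%
multi-category) are chosen so that every reasoning behavior occurs many
times per graph while a brute-force oracle scan stays fast; validation
batteries run 20 such graphs (up to ~260 nodes and ~1,500 edges) and
1,000 random queries, comparing the engine's knowledge-edge sets with the
index-free oracle exactly.

The generator emulates the *semantics* of real Biolink KGs, not their
statistics: content is synthetic, degree distributions are roughly
uniform rather than scale-free, and vocabularies are tiny. Passing tests
therefore demonstrate correctness of the reasoning and indexing logic,
not performance or robustness on multi-million-edge graphs (the design —
dictionary postings plus precomputed closures — is the same one that
scales, but nothing here measures that).

The oracle is written against the parsed graph document and never touches
the adjacency index; expansion, per-edge matching, and constraint
evaluation are implemented independently on each side. Only the final
answer-set assembly (payload formatting) is shared, so that "identical
answers" is well-defined down to the rendered structure.

## Numerical and determinism choices

* Generated edge ids are content hashes (FNV-1a, two 32-bit passes over
  subject, predicate, object, source, and sorted properties), so ids are
  stable across rebuilds of the same content.
* All emitted collections are sorted (results, edge ids, cluster members,
  meta-edges, id prefixes); reruns and snapshot restores are
  byte-identical.
* TSV list cells use the pipe separator with no escaping; cells containing
  literal pipes are out of scope. Property values are read as strings
  unless a `trapi_attribute_map` entry declares them numeric, avoiding
  silent type drift between the TSV and JSON Lines dialects.
* Test-triple exemplars are the lexicographically smallest
  (subject id, object id, edge id) per meta-edge.
* The generator and query sampler save and restore the session RNG state,
  so library calls never perturb user randomness.

## Limitations

One-hop queries only (no multi-hop planning, scoring, or TRAPI qualifier
constraints); fully memory-resident with no incremental updates after
build; meta-edges advertise asserted most-specific categories without
hierarchy roll-up (recoverable through the schema); the HTTP layer is a
single-process server intended for local use — for production the
immutable post-build state makes any multi-process manager safe, but none
is mandated.
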