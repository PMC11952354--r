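# Shared fixtures: the mini schema and a hand-built 12-node/18-edge graph
# exercising every reasoning behavior (symmetric edges, an inverse-asserted
# edge, a 3-level subclass chain, an equivalence pair, an uncategorized node).

mini_schema <- function() {
  load_schema(system.file("extdata", "mini_schema.yaml", package = "kghop"))
}

mini_nodes <- function() {
  data.table::data.table(
    id = c("DRUG:aspirin", "CHEM:asa", "DRUG:tylenol", "GENE:g1", "GENE:g2",
           "GENE:g3", "DIS:headache", "DIS:migraine", "DIS:cluster", "DIS:flu",
           "CHEM:caffeine", "NODE:uncat"),
    name = c("aspirin", "acetylsalicylic acid", "tylenol", "gene 1", "gene 2",
             "gene 3", "headache", "migraine", "cluster headache", "flu",
             "caffeine", "mystery"),
    categories = list("Drug", "ChemicalEntity", "Drug", "Gene", "Gene", "Gene",
                      "Disease", "Disease", "Disease", "Disease",
                      "ChemicalEntity", character()),
    equivalent_identifiers = list(
      c("DRUG:aspirin", "EQV:asa"), c("CHEM:asa", "EQV:asa"), character(),
      character(), character(), character(), character(), character(),
      character(), character(), character(), character()
    ),
    properties = c(list(list(xref = "CHEBI:15365")), replicate(11, list(), simplify = FALSE))
  )
}

mini_edges <- function() {
  e <- function(id, s, p, o, pks = NA_character_, props = list()) {
    list(id = id, subject = s, predicate = p, object = o, pks = pks, props = props)
  }
  rows <- list(
    e("e01", "DRUG:aspirin", "interacts_with", "GENE:g1", "infores:drugbank",
      list(publications = c("PMID:1", "PMID:2"))),
    e("e02", "GENE:g1", "interacts_with", "GENE:g2", "infores:string"),
    e("e03", "DRUG:tylenol", "treats", "DIS:headache", "infores:drugcentral"),
    e("e04", "DIS:migraine", "treated_by", "DRUG:aspirin", "infores:semmeddb",
      list(publications = "PMID:3")),
    e("e05", "DIS:migraine", "subclass_of", "DIS:headache", "infores:mondo"),
    e("e06", "DIS:cluster", "subclass_of", "DIS:migraine", "infores:mondo"),
    e("e07", "DRUG:tylenol", "treats", "DIS:cluster", "infores:drugcentral"),
    e("e08", "CHEM:asa", "affects", "GENE:g2", "infores:ctd"),
    e("e09", "CHEM:caffeine", "interacts_with", "DRUG:aspirin", "infores:drugbank"),
    e("e10", "GENE:g2", "affects", "DIS:flu", "infores:ctd"),
    e("e11", "DRUG:aspirin", "treats", "DIS:flu", "infores:drugbank",
      list(score = "0.9")),
    e("e12", "GENE:g3", "interacts_with", "GENE:g1", "infores:string"),
    e("e13", "CHEM:caffeine", "affects", "DIS:headache", "infores:semmeddb"),
    e("e14", "NODE:uncat", "related_to", "GENE:g3", NA_character_),
    e("e15", "DRUG:tylenol", "interacts_with", "GENE:g3", "infores:drugbank"),
    e("e16", "DIS:flu", "treated_by", "CHEM:caffeine", "infores:semmeddb"),
    e("e17", "GENE:g3", "affects", "DIS:migraine", "infores:ctd"),
    e("e18", "CHEM:asa", "interacts_with", "GENE:g1", "infores:drugbank",
      list(publications = "PMID:4"))
  )
  data.table::data.table(
    id = vapply(rows, `[[`, character(1), "id"),
    subject = vapply(rows, `[[`, character(1), "subject"),
    predicate = vapply(rows, `[[`, character(1), "predicate"),
    object = vapply(rows, `[[`, character(1), "object"),
    primary_knowledge_source = vapply(rows, `[[`, character(1), "pks"),
    properties = lapply(rows, `[[`, "props")
  )
}

mini_graph <- function() {
  kg_graph(mini_nodes(), mini_edges(), provenance = list(source = "helper"))
}

# fully built reasoning context for the mini graph (index built with the
# root-category warning for NODE:uncat suppressed)
mini_context <- function() {
  schema <- mini_schema()
  graph <- mini_graph()
  eqmap <- build_equivalence_map(graph$nodes)
  closure <- compute_subclass_closure(graph)
  index <- suppressWarnings(build_index(graph, schema))
  list(schema = schema, graph = graph, eqmap = eqmap, closure = closure, index = index)
}

one_hop <- function(s_ids = NULL, s_cats = NULL, o_ids = NULL, o_cats = NULL,
                    predicates = NULL, constraints = NULL) {
  n0 <- list(); n1 <- list()
  if (!is.null(s_ids)) n0$ids <- s_ids
  if (!is.null(s_cats)) n0$categories <- s_cats
  if (!is.null(o_ids)) n1$ids <- o_ids
  if (!is.null(o_cats)) n1$categories <- o_cats
  qe <- list(subject = "n0", object = "n1")
  if (!is.null(predicates)) qe$predicates <- predicates
  if (!is.null(constraints)) qe$attribute_constraints <- constraints
  list(nodes = list(n0 = n0, n1 = n1), edges = list(e0 = qe))
}

# random rooted DAG as a schema document: node 1 is the root, every later
# node gets 1-2 parents among its predecessors
random_dag_schema <- function(n, seed) {
  withr::with_seed(seed, {
    labels <- sprintf("N%03d", seq_len(n))
    cats <- list(list(name = labels[1L]))
    edges <- list()
    for (i in 2:n) {
      k <- sample(1:2, 1L)
      parents <- labels[sample.int(i - 1L, min(k, i - 1L))]
      cats[[i]] <- list(name = labels[i], parents = as.list(parents))
      for (p in parents) edges[[length(edges) + 1L]] <- c(p, labels[i])
    }
    list(
      doc = list(categories = cats,
                 predicates = list(list(name = "related_to"))),
      labels = labels,
      edges = do.call(rbind, edges)  # parent -> child
    )
  })
}

expect_same_answers <- function(engine_ans, oracle_ans) {
  expect_identical(answer_edge_ids(engine_ans), answer_edge_ids(oracle_ans))
}
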