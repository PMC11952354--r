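test_that("inverse-asserted edges are stored flipped to canonical orientation", {
  sch <- mini_schema()
  nodes <- data.table::data.table(
    id = c("CHEBI:1", "MONDO:7"), name = c("drug", "disease"),
    categories = list("Drug", "Disease"),
    equivalent_identifiers = list(character(), character()),
    properties = list(list(), list())
  )
  edges <- data.table::data.table(
    id = "e1", subject = "CHEBI:1", predicate = "treated_by", object = "MONDO:7",
    primary_knowledge_source = NA_character_, properties = list(list())
  )
  idx <- build_index(kg_graph(nodes, edges), sch)
  stored <- idx$edges[1L]
  expect_identical(stored$subject, "MONDO:7")
  expect_identical(stored$predicate, "treats")
  expect_identical(stored$object, "CHEBI:1")
  expect_true(stored$flipped)
  expect_identical(idx$stats$n_edges_flipped, 1L)
  # reachable from both endpoints
  expect_identical(lookup(idx, "MONDO:7", "out", predicates = "treats"), "e1")
  expect_identical(lookup(idx, "CHEBI:1", "in", predicates = "treats"), "e1")
  expect_identical(lookup(idx, "MONDO:7", "out", categories = "Drug"), "e1")
})

test_that("symmetric edges are retrievable in the out direction from both nodes", {
  ctx <- mini_context()
  expect_true("e02" %in% lookup(ctx$index, "GENE:g1", "out", predicates = "interacts_with"))
  expect_true("e02" %in% lookup(ctx$index, "GENE:g2", "out", predicates = "interacts_with"))
})

test_that("empty graphs build empty indexes with zeroed counters", {
  idx <- build_index(kg_graph(kghop:::empty_nodes_dt(), kghop:::empty_edges_dt()),
                     mini_schema())
  expect_identical(idx$stats$n_nodes, 0L)
  expect_identical(idx$stats$n_edges, 0L)
  expect_identical(lookup(idx, "anything"), character())
})

test_that("categoryless nodes are assigned the category root with a warning", {
  sch <- mini_schema()
  g <- mini_graph()
  expect_warning(idx <- build_index(g, sch), regexp = "NamedThing")
  expect_identical(idx$category_of[["NODE:uncat"]], "NamedThing")
  # most-specific categories drop redundant ancestors
  expect_identical(kghop:::most_specific_categories(sch, c("ChemicalEntity", "Drug")),
                   "Drug")
})

test_that("edges with missing endpoints or unknown predicates are skipped and counted", {
  sch <- mini_schema()
  nodes <- mini_nodes()
  edges <- rbind(
    mini_edges(),
    data.table::data.table(
      id = c("bad1", "bad2"),
      subject = c("GHOST:1", "GENE:g1"),
      predicate = c("treats", "mystery_link"),
      object = c("GENE:g1", "GENE:g2"),
      primary_knowledge_source = NA_character_,
      properties = list(list(), list())
    )
  )
  idx <- suppressWarnings(build_index(kg_graph(nodes, edges), sch))
  expect_identical(idx$stats$n_edges, 18L)
  expect_identical(idx$stats$n_edges_skipped_missing_endpoint, 1L)
  expect_identical(idx$stats$n_edges_skipped_unknown_predicate, 1L)
})

test_that("lookup equals a brute-force incidence scan on the mini fixture", {
  ctx <- mini_context()
  stored <- ctx$index$edges
  for (node in ctx$graph$nodes$id) {
    expect_setequal(
      lookup(ctx$index, node, "any"),
      stored$id[stored$subject == node | stored$object == node]
    )
  }
  expect_identical(lookup(ctx$index, "GHOST:404"), character())
  expect_identical(
    lookup(ctx$index, "DRUG:aspirin", predicates = "subclass_of"), character()
  )
})

test_that("lookup with direction any is the union of out and in", {
  ctx <- mini_context()
  for (node in c("DRUG:aspirin", "GENE:g2", "DIS:headache")) {
    expect_setequal(
      lookup(ctx$index, node, "any"),
      union(lookup(ctx$index, node, "out"), lookup(ctx$index, node, "in"))
    )
  }
})

test_that("edge conservation: every stored edge is posted under both endpoints", {
  fx <- generate_kg(fixture_spec(n_nodes = 60L, n_edges = 150L, seed = 31L))
  idx <- build_index(fx$graph, demo_schema())
  out_ids <- unlist(lapply(fx$graph$nodes$id, function(nd) lookup(idx, nd, "out")))
  expect_setequal(unique(out_ids), idx$edges$id)
  for (i in seq_len(nrow(idx$edges))) {
    expect_true(idx$edges$id[i] %in% lookup(idx, idx$edges$subject[i]))
    expect_true(idx$edges$id[i] %in% lookup(idx, idx$edges$object[i]))
  }
})

test_that("subclass closure chains transitively and honors depth limits", {
  nodes <- data.table::data.table(
    id = c("A", "B", "C"), name = NA_character_,
    categories = list("Disease", "Disease", "Disease"),
    equivalent_identifiers = list(character(), character(), character()),
    properties = list(list(), list(), list())
  )
  edges <- data.table::data.table(
    id = c("s1", "s2"), subject = c("C", "B"), predicate = "subclass_of",
    object = c("B", "A"), primary_knowledge_source = NA_character_,
    properties = list(list(), list())
  )
  g <- kg_graph(nodes, edges)
  cl <- compute_subclass_closure(g)
  expect_setequal(cl$descendants_of[["A"]], c("A", "B", "C"))
  cl1 <- compute_subclass_closure(g, max_depth = 1L)
  expect_setequal(cl1$descendants_of[["A"]], c("A", "B"))
  # external pairs union with in-graph edges
  cle <- compute_subclass_closure(g, external_pairs = cbind("D", "C"))
  expect_setequal(cle$descendants_of[["A"]], c("A", "B", "C", "D"))
  # cycles warn and members become mutual descendants
  cyc <- kg_graph(nodes, data.table::data.table(
    id = c("s1", "s2"), subject = c("A", "B"), predicate = "subclass_of",
    object = c("B", "A"), primary_knowledge_source = NA_character_,
    properties = list(list(), list())
  ))
  expect_warning(clc <- compute_subclass_closure(cyc), regexp = "cycle")
  expect_setequal(clc$descendants_of[["A"]], c("A", "B"))
  expect_setequal(clc$descendants_of[["B"]], c("A", "B"))
})

test_that("subclass closure equals reverse reachability on a random 100-node DAG", {
  withr::with_seed(55L, {
    n <- 100L
    ids <- sprintf("C:%03d", seq_len(n))
    child <- character(); parent <- character()
    for (i in 2:n) {
      for (p in ids[sample.int(i - 1L, sample(1:2, 1L), replace = TRUE)]) {
        child <- c(child, ids[i]); parent <- c(parent, p)
      }
    }
    nodes <- data.table::data.table(
      id = ids, name = NA_character_,
      categories = replicate(n, "Disease", simplify = FALSE),
      equivalent_identifiers = replicate(n, character(), simplify = FALSE),
      properties = replicate(n, list(), simplify = FALSE)
    )
    edges <- data.table::data.table(
      id = sprintf("s%04d", seq_along(child)), subject = child,
      predicate = "subclass_of", object = parent,
      primary_knowledge_source = NA_character_,
      properties = replicate(length(child), list(), simplify = FALSE)
    )
    cl <- compute_subclass_closure(kg_graph(nodes, edges))
    ig <- igraph::graph_from_edgelist(cbind(parent, child), directed = TRUE)
    for (x in ids) {
      expect_setequal(cl$descendants_of[[x]],
                      names(igraph::subcomponent(ig, x, mode = "out")))
    }
  })
})

test_that("index snapshots restore to identical lookup behavior", {
  ctx <- mini_context()
  path <- withr::local_tempfile(fileext = ".snapshot")
  save_index(ctx$index, ctx$closure, path)
  restored <- load_index(path)
  # exhaustive key enumeration: every node x direction x category x predicate
  sch <- ctx$schema
  for (node in c(ctx$graph$nodes$id, "GHOST:1")) {
    for (dir in c("out", "in", "any")) {
      expect_identical(
        sort(lookup(restored$index, node, dir)),
        sort(lookup(ctx$index, node, dir))
      )
      for (cat in names(sch$categories)) {
        for (pred in names(sch$predicates)) {
          expect_identical(
            sort(lookup(restored$index, node, dir, categories = cat, predicates = pred)),
            sort(lookup(ctx$index, node, dir, categories = cat, predicates = pred))
          )
        }
      }
    }
  }
  expect_identical(restored$closure$descendants_of, ctx$closure$descendants_of)
})

test_that("snapshot loading rejects corrupt or missing files", {
  path <- withr::local_tempfile(fileext = ".snapshot")
  ctx <- mini_context()
  save_index(ctx$index, ctx$closure, path)
  raw <- readBin(path, "raw", n = file.size(path))
  writeBin(raw[seq_len(20L)], path)  # truncate
  expect_error(load_index(path), class = "kghop_load_error")
  expect_error(load_index(file.path(tempdir(), "no_such.snapshot")),
               class = "kghop_load_error")
  # an RDS that is not a snapshot
  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_index(other), class = "kghop_load_error")
  # empty index round-trips
  empty_idx <- build_index(kg_graph(kghop:::empty_nodes_dt(), kghop:::empty_edges_dt()),
                           mini_schema())
  p2 <- withr::local_tempfile()
  save_index(empty_idx, NULL, p2)
  expect_identical(load_index(p2)$index$stats$n_edges, 0L)
})
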