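test_that("query validation enforces the one-hop structure", {
  sch <- mini_schema()
  ok <- validate_query(one_hop(s_ids = "DRUG:aspirin", o_cats = "Gene",
                               predicates = "interacts_with"), sch)
  expect_s3_class(ok, "kg_query")
  expect_identical(ok$nodes$n0$ids, "DRUG:aspirin")
  # biolink: prefixes are normalized
  ok2 <- validate_query(one_hop(s_ids = "X:1", o_cats = "biolink:Gene",
                                predicates = "biolink:treats"), sch)
  expect_identical(ok2$nodes$n1$categories, "Gene")
  expect_identical(ok2$edges$e0$predicates, "treats")
  # TRAPI envelope accepted
  ok3 <- validate_query(list(message = list(query_graph = one_hop(s_ids = "X:1"))), sch)
  expect_s3_class(ok3, "kg_query")

  two_edges <- one_hop(s_ids = "X:1")
  two_edges$edges$e1 <- two_edges$edges$e0
  expect_error(validate_query(two_edges, sch), class = "kghop_query_structure_error")
  three_nodes <- one_hop(s_ids = "X:1")
  three_nodes$nodes$n2 <- list()
  expect_error(validate_query(three_nodes, sch), class = "kghop_query_structure_error")
  expect_error(validate_query(one_hop(s_cats = "Drug", o_cats = "Gene"), sch),
               class = "kghop_unpinned_query_error")
  expect_error(validate_query(one_hop(s_ids = "X:1", o_cats = "NotACategory"), sch),
               class = "kghop_unknown_element")
  expect_error(validate_query(one_hop(s_ids = "X:1", predicates = "frobnicates"), sch),
               class = "kghop_unknown_element")
})

test_that("pinned ids expand through representatives and subclass descendants", {
  ctx <- mini_context()
  # subclass chain: headache <- migraine <- cluster
  exp1 <- expand_pinned_ids("DIS:headache", ctx$eqmap, ctx$closure)
  expect_identical(
    exp1,
    c("DIS:headache" = "DIS:headache", "DIS:migraine" = "DIS:headache",
      "DIS:cluster" = "DIS:headache")
  )
  # equivalence: expansion keeps the queried id and adds the cluster
  # representative (the cluster's smallest node id, CHEM:asa)
  exp2 <- expand_pinned_ids("DRUG:aspirin", ctx$eqmap, ctx$closure)
  expect_setequal(names(exp2), c("DRUG:aspirin", "CHEM:asa"))
  expect_identical(unique(unname(exp2)), "DRUG:aspirin")
  # unknown ids expand to themselves
  expect_identical(expand_pinned_ids("X:404", ctx$eqmap, ctx$closure),
                   c("X:404" = "X:404"))
  # first query id wins ties
  exp3 <- expand_pinned_ids(c("DIS:migraine", "DIS:cluster"), ctx$eqmap, ctx$closure)
  expect_identical(unname(exp3["DIS:cluster"]), "DIS:migraine")
})

test_that("attribute constraints follow any-value/all-constraint semantics", {
  edges <- data.table::data.table(
    id = c("a", "b", "c"),
    subject = "X", predicate = "treats", object = "Y",
    primary_knowledge_source = c("infores:drugbank", "infores:ctd", NA),
    flipped = FALSE,
    properties = list(
      list(publications = c("PMID:123"), score = "0.7"),
      list(score = "0.2"),
      list(publications = "PMC:9")
    )
  )
  keep <- function(cons) apply_attribute_constraints(edges, cons)$id
  expect_identical(
    keep(list(list(name = "knowledge_source", operator = "==", value = "infores:drugbank"))),
    "a"
  )
  expect_identical(
    keep(list(list(name = "publications", operator = "matches", value = "PMID:"))), "a"
  )
  expect_identical(keep(list(list(name = "score", operator = ">", value = "0.5"))), "a")
  expect_identical(keep(list(list(name = "score", operator = "<", value = "0.5"))), "b")
  # negated: missing property passes
  expect_identical(
    keep(list(list(name = "score", operator = ">", value = "0.5", negated = TRUE))),
    c("b", "c")
  )
  # all constraints must pass
  expect_identical(
    keep(list(
      list(name = "publications", operator = "matches", value = "PMID:"),
      list(name = "score", operator = ">", value = "0.9")
    )),
    character()
  )
  expect_error(
    keep(list(list(name = "publications", operator = "matches", value = "[["))),
    class = "kghop_constraint_error"
  )
})

test_that("randomized constraints agree with an independent evaluator", {
  # plain predicate-logic reference, written against raw records
  ref_eval <- function(props, pks, cons) {
    all(vapply(cons, function(ac) {
      v <- if (identical(ac$name, "knowledge_source")) {
        if (is.na(pks)) character() else pks
      } else if (ac$name %in% names(props)) as.character(props[[ac$name]]) else character()
      r <- if (!length(v)) FALSE
      else if (ac$operator == "==") any(v == ac$value)
      else if (ac$operator == "matches") any(grepl(ac$value, v))
      else {
        vn <- suppressWarnings(as.numeric(v)); cn <- suppressWarnings(as.numeric(ac$value))
        if (!anyNA(vn) && !is.na(cn)) {
          if (ac$operator == ">") any(vn > cn) else any(vn < cn)
        } else if (ac$operator == ">") any(v > ac$value) else any(v < ac$value)
      }
      if (isTRUE(ac$negated)) !r else r
    }, logical(1)))
  }
  withr::with_seed(77L, {
    for (rep in 1:25) {
      n <- 12L
      props <- lapply(seq_len(n), function(i) {
        p <- list()
        if (runif(1) < 0.6) p$score <- sprintf("%.2f", runif(1))
        if (runif(1) < 0.5) p$publications <- sprintf("PMID:%d", sample.int(50L, sample(1:3, 1L)))
        p
      })
      pks <- ifelse(runif(n) < 0.8, sample(c("infores:a", "infores:b"), n, replace = TRUE),
                    NA_character_)
      edges <- data.table::data.table(
        id = sprintf("e%02d", seq_len(n)), subject = "X", predicate = "treats",
        object = "Y", primary_knowledge_source = pks, flipped = FALSE,
        properties = props
      )
      cons <- list(list(
        name = sample(c("score", "publications", "knowledge_source"), 1L),
        operator = sample(c("==", ">", "<", "matches"), 1L),
        value = sample(c("0.5", "PMID:1", "infores:a"), 1L),
        negated = runif(1) < 0.4
      ))
      got <- apply_attribute_constraints(edges, cons)$id
      want <- edges$id[vapply(seq_len(n), function(i) ref_eval(props[[i]], pks[i], cons),
                              logical(1))]
      expect_identical(got, want)
    }
  })
})

test_that("the drug-protein style query matches the brute-force oracle on the mini KG", {
  ctx <- mini_context()
  qg <- one_hop(s_ids = "DRUG:aspirin", o_cats = "Gene", predicates = "interacts_with")
  eng <- answer_query(qg, ctx$index, ctx$schema, ctx$eqmap, ctx$closure)
  orc <- brute_force_answer(ctx$graph, ctx$schema, ctx$eqmap, ctx$closure, qg)
  # equivalence reasoning pulls in the representative's edge (e18) next to
  # the direct match (e01)
  expect_setequal(answer_edge_ids(eng), c("e01", "e18"))
  expect_equal(unclass(eng), unclass(orc))
  # bindings carry query_id provenance for equivalence matches
  ids <- vapply(eng$results, function(r) r$node_bindings$n0[[1L]]$id, character(1))
  qids <- lapply(eng$results, function(r) r$node_bindings$n0[[1L]]$query_id)
  expect_true(any(ids == "CHEM:asa" &
                    vapply(qids, identical, logical(1), "DRUG:aspirin")))
})

test_that("the root predicate matches every edge incident to the expansion set", {
  ctx <- mini_context()
  qg <- one_hop(s_ids = "GENE:g2", predicates = "related_to")
  got <- answer_edge_ids(answer_query(qg, ctx$index, ctx$schema, ctx$eqmap, ctx$closure))
  stored <- ctx$index$edges
  expect_setequal(got, stored$id[stored$subject == "GENE:g2" | stored$object == "GENE:g2"])
  # omitting predicates entirely behaves the same
  qg2 <- one_hop(s_ids = "GENE:g2")
  expect_identical(
    answer_edge_ids(answer_query(qg2, ctx$index, ctx$schema, ctx$eqmap, ctx$closure)), got
  )
})

test_that("queries pinned on absent ids return empty answer sets", {
  ctx <- mini_context()
  ans <- answer_query(one_hop(s_ids = "GHOST:1"), ctx$index, ctx$schema,
                      ctx$eqmap, ctx$closure)
  expect_length(ans$results, 0L)
  expect_length(ans$knowledge_nodes, 0L)
  expect_length(ans$knowledge_edges, 0L)
})

test_that("subclass chaining answers apex queries with descendant edges", {
  ctx <- mini_context()
  # everything that treats headache, including treatments of its subtypes,
  # and the inverse-asserted migraine-treated_by-aspirin edge
  qg <- one_hop(s_cats = "ChemicalEntity", o_ids = "DIS:headache", predicates = "treats")
  expect_setequal(
    answer_edge_ids(answer_query(qg, ctx$index, ctx$schema, ctx$eqmap, ctx$closure)),
    c("e03", "e04", "e07")
  )
})

test_that("symmetric predicates ignore query orientation", {
  ctx <- mini_context()
  for (nid in c("GENE:g1", "DRUG:aspirin", "CHEM:caffeine")) {
    fwd <- one_hop(s_ids = nid, predicates = "interacts_with")
    rev <- one_hop(o_ids = nid, predicates = "interacts_with")
    expect_identical(
      answer_edge_ids(answer_query(fwd, ctx$index, ctx$schema, ctx$eqmap, ctx$closure)),
      answer_edge_ids(answer_query(rev, ctx$index, ctx$schema, ctx$eqmap, ctx$closure))
    )
  }
})

test_that("inverse-phrased queries equal canonical queries with swapped endpoints", {
  ctx <- mini_context()
  for (nid in c("DIS:flu", "DIS:migraine", "DRUG:tylenol")) {
    canon <- one_hop(o_ids = nid, predicates = "treats")      # ? treats nid
    inv <- one_hop(s_ids = nid, predicates = "treated_by")    # nid treated_by ?
    expect_identical(
      answer_edge_ids(answer_query(canon, ctx$index, ctx$schema, ctx$eqmap, ctx$closure)),
      answer_edge_ids(answer_query(inv, ctx$index, ctx$schema, ctx$eqmap, ctx$closure))
    )
  }
})

test_that("constraints are monotone and predicate hierarchy is respected", {
  ctx <- mini_context()
  base <- one_hop(s_ids = "DRUG:aspirin")
  base_ids <- answer_edge_ids(answer_query(base, ctx$index, ctx$schema,
                                           ctx$eqmap, ctx$closure))
  with_pred <- one_hop(s_ids = "DRUG:aspirin", predicates = "treats")
  with_cat <- one_hop(s_ids = "DRUG:aspirin", o_cats = "Gene")
  with_attr <- one_hop(s_ids = "DRUG:aspirin", constraints = list(
    list(name = "knowledge_source", operator = "==", value = "infores:drugbank")
  ))
  for (qg in list(with_pred, with_cat, with_attr)) {
    expect_true(all(
      answer_edge_ids(answer_query(qg, ctx$index, ctx$schema, ctx$eqmap, ctx$closure))
      %in% base_ids
    ))
  }
  # ancestor predicate returns a superset of each descendant predicate
  sch <- ctx$schema
  for (anc in c("related_to", "affects")) {
    anc_ids <- answer_edge_ids(answer_query(
      one_hop(s_ids = "DRUG:aspirin", predicates = anc),
      ctx$index, sch, ctx$eqmap, ctx$closure
    ))
    for (desc in setdiff(descendants(sch, anc, "predicate"), anc)) {
      desc_ids <- answer_edge_ids(answer_query(
        one_hop(s_ids = "DRUG:aspirin", predicates = desc),
        ctx$index, sch, ctx$eqmap, ctx$closure
      ))
      expect_true(all(desc_ids %in% anc_ids))
    }
  }
})

test_that("TRAPI rendering preserves bindings and maps attributes", {
  ctx <- mini_context()
  amap <- list(publications = list(attribute_type_id = "biolink:publications"))
  qg <- one_hop(s_ids = "DRUG:aspirin", o_cats = "Gene", predicates = "interacts_with")
  ans <- answer_query(qg, ctx$index, ctx$schema, ctx$eqmap, ctx$closure,
                      attribute_map = amap)
  msg <- as_trapi_message(ans, validate_query(qg, ctx$schema))
  expect_named(msg, "message")
  expect_setequal(names(msg$message), c("query_graph", "knowledge_graph", "results"))
  e1 <- msg$message$knowledge_graph$edges[["e01"]]
  types <- vapply(e1$attributes, `[[`, character(1), "attribute_type_id")
  expect_true("biolink:publications" %in% types)
  nb <- msg$message$results[[1L]]$node_bindings
  expect_setequal(names(nb), c("n0", "n1"))
  expect_named(msg$message$results[[1L]]$analyses[[1L]], "edge_bindings")
})
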