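#' Validate and normalize a one-hop query graph
#'
#' A query graph has exactly two query nodes joined by exactly one query
#' edge. Nodes can be constrained by identifier (`ids`) and category
#' (`categories`); the edge by predicate (`predicates`) and attribute
#' constraints. At least one query node must be pinned (non-empty `ids`) —
#' fully unconstrained scans are rejected.
#'
#' Accepts either the plain structure
#' `list(nodes = list(n0 = list(ids = ...), n1 = ...), edges = list(e0 =
#' list(subject = "n0", object = "n1", predicates = ...)))` or a TRAPI-style
#' message (`list(message = list(query_graph = ...))`). Category and
#' predicate labels are `biolink:`-prefix-normalized and checked against the
#' schema.
#'
#' @param qg Query graph (list) or TRAPI message containing one.
#' @param schema A `kg_schema`.
#' @return The normalized query graph, classed `kg_query`.
#' @export
validate_query <- function(qg, schema) {
  if (!is.null(qg$message)) qg <- qg$message$query_graph
  if (!is.null(qg$query_graph)) qg <- qg$query_graph
  if (is.null(qg$nodes) || is.null(qg$edges)) {
    abort_query_structure("query graph must contain 'nodes' and 'edges'")
  }
  if (length(qg$nodes) != 2L) {
    abort_query_structure(sprintf(
      "one-hop query graph must have exactly 2 query nodes, found %d", length(qg$nodes)
    ))
  }
  if (length(qg$edges) != 1L) {
    abort_query_structure(sprintf(
      "one-hop query graph must have exactly 1 query edge, found %d", length(qg$edges)
    ))
  }
  qe <- qg$edges[[1L]]
  nkeys <- names(qg$nodes)
  if (is.null(qe$subject) || is.null(qe$object) ||
      !qe$subject %in% nkeys || !qe$object %in% nkeys) {
    abort_query_structure("query edge endpoints must reference existing query nodes")
  }
  if (qe$subject == qe$object) {
    abort_query_structure("query edge endpoints must reference distinct query nodes")
  }
  qg$nodes <- lapply(qg$nodes, function(qn) {
    qn$ids <- as.character(qn$ids %||% character())
    qn$categories <- strip_label_prefix(as.character(qn$categories %||% character()))
    for (cat in qn$categories) {
      if (!cat %in% names(schema$categories)) abort_unknown_element(cat, "category")
    }
    qn
  })
  qe$predicates <- strip_label_prefix(as.character(qe$predicates %||% character()))
  for (p in qe$predicates) {
    if (!p %in% names(schema$predicates)) abort_unknown_element(p, "predicate")
  }
  qe$attribute_constraints <- lapply(qe$attribute_constraints %||% list(), function(ac) {
    ac$name <- ac$name %||% ac$id
    if (is.null(ac$name)) abort_constraint("attribute constraint missing 'name'")
    ac$operator <- ac$operator %||% "=="
    if (!ac$operator %in% c("==", ">", "<", "matches")) {
      abort_constraint(sprintf("unsupported constraint operator '%s'", ac$operator))
    }
    if (is.null(ac$value)) abort_constraint("attribute constraint missing 'value'")
    ac$negated <- isTRUE(ac$negated) || isTRUE(ac$not)
    ac
  })
  qg$edges[[1L]] <- qe
  if (!any(vapply(qg$nodes, function(qn) length(qn$ids) > 0L, logical(1)))) {
    abort_unpinned_query("at least one query node must be pinned with ids")
  }
  structure(qg, class = "kg_query")
}

#' Expand pinned query identifiers
#'
#' Applies the two concept-level reasoning behaviors to a list of queried
#' CURIEs: each id is resolved to its equivalence-cluster representative
#' and expanded to all subclass descendants of the representative and of
#' the id itself. The expansion always contains the queried id (a direct
#' match is never lost to equivalence redirection). The returned mapping
#' records which queried id produced each concrete id (the first query id
#' wins ties, in query order); ids without equivalents or subclasses
#' expand to themselves.
#'
#' @param ids Character vector of queried CURIEs, in query order.
#' @param eqmap A `kg_eqmap` or `NULL`.
#' @param closure A `kg_closure` or `NULL`.
#' @return Named character vector: names are concrete CURIEs, values the
#'   originating query CURIE.
#' @export
expand_pinned_ids <- function(ids, eqmap, closure) {
  out <- character()
  for (qid in ids) {
    rep <- eq_representative(eqmap, qid)
    concrete <- unique(c(closure_descendants(closure, qid),
                         closure_descendants(closure, rep)))
    new <- setdiff(concrete, names(out))
    out[new] <- qid
  }
  out
}

#' Filter edges by attribute constraints
#'
#' An edge passes when all constraints pass. A constraint on property `p`
#' passes if any value of `p` (list values are tested element-wise)
#' satisfies the operator against the constraint value; `negated` inverts
#' the outcome. A missing property fails a non-negated constraint and passes
#' a negated one. `>`/`<` compare numerically when both sides parse as
#' numbers and lexicographically otherwise; `==` is string equality (set
#' membership for list-valued constraints); `matches` is regular-expression
#' search. The constraint name `knowledge_source` is an alias for the
#' `primary_knowledge_source` core field.
#'
#' @param edges Stored-edge `data.table` (rows of `index$edges`) or a
#'   `kg_graph` edge table.
#' @param constraints List of attribute constraints (`name`, `operator`,
#'   `value`, `negated`).
#' @return The rows of `edges` that pass all constraints.
#' @export
apply_attribute_constraints <- function(edges, constraints) {
  if (!length(constraints) || !nrow(edges)) return(edges)
  pass <- vapply(seq_len(nrow(edges)), function(i) {
    all(vapply(constraints, function(ac) {
      edge_passes_constraint(
        edges$properties[[i]], edges$primary_knowledge_source[i], ac
      )
    }, logical(1)))
  }, logical(1))
  edges[pass]
}

edge_property_values <- function(properties, pks, name) {
  if (name %in% c("primary_knowledge_source", "knowledge_source")) {
    if (is.na(pks)) NULL else pks
  } else if (name %in% names(properties)) {
    properties[[name]]
  } else {
    NULL
  }
}

edge_passes_constraint <- function(properties, pks, ac) {
  vals <- edge_property_values(properties, pks, ac$name)
  raw <- if (is.null(vals) || !length(vals)) {
    FALSE
  } else {
    constraint_op(as.character(unlist(vals, use.names = FALSE)), ac$operator,
                  as.character(unlist(ac$value, use.names = FALSE)))
  }
  if (isTRUE(ac$negated)) !raw else raw
}

constraint_op <- function(vals, op, cv) {
  switch(op,
    "==" = any(vals %in% cv),
    ">" = ,
    "<" = {
      nv <- suppressWarnings(as.numeric(vals))
      nc <- suppressWarnings(as.numeric(cv[1L]))
      if (!anyNA(nv) && !is.na(nc)) {
        if (op == ">") any(nv > nc) else any(nv < nc)
      } else {
        if (op == ">") any(vals > cv[1L]) else any(vals < cv[1L])
      }
    },
    "matches" = {
      hit <- tryCatch(
        suppressWarnings(any(vapply(cv, function(pat) any(grepl(pat, vals)), logical(1)))),
        error = function(e) abort_constraint(
          sprintf("invalid regular expression in constraint: %s", conditionMessage(e))
        )
      )
      hit
    },
    abort_constraint(sprintf("unsupported constraint operator '%s'", op))
  )
}

# Maps query predicates to canonical predicates with the orientation in
# which stored edges must be read. Returns canonical predicate sets for
# forward (query subject = stored subject) and reverse reading. Symmetric
# stored predicates land in both sets. A *query* predicate that is itself
# symmetric — or the predicate root, whose query imposes no edge-type
# constraint at all — is direction-free: all of its descendants match in
# both orientations.
canonical_match_sets <- function(schema, predicates) {
  if (!length(predicates)) predicates <- schema$predicate_root
  fwd <- character(); rev <- character()
  for (p in predicates) {
    direction_free <- is_symmetric_predicate(schema, p) ||
      identical(p, schema$predicate_root)
    for (d in descendants(schema, p, "predicate")) {
      cf <- canonical_form(schema, d)
      if (direction_free || is_symmetric_predicate(schema, cf$predicate)) {
        fwd <- c(fwd, cf$predicate); rev <- c(rev, cf$predicate)
      } else if (cf$flipped) {
        rev <- c(rev, cf$predicate)
      } else {
        fwd <- c(fwd, cf$predicate)
      }
    }
  }
  list(forward = unique(fwd), reverse = unique(rev))
}

#' Answer a one-hop query
#'
#' Pattern-matches a validated one-hop query graph against the adjacency
#' index, applying the five built-in reasoning behaviors: category and
#' predicate hierarchy expansion, predicate symmetry, predicate canonicity
#' (edges asserted via an inverse predicate match queries in either
#' phrasing), concept equivalence, and transitive concept subclass
#' chaining of pinned identifiers. All matching subgraphs are returned —
#' not only direct matches.
#'
#' Pipeline: pinned ids expand through [expand_pinned_ids()]; query
#' categories expand to schema descendant sets; query predicates map
#' through [canonical_form()] into same-direction and flipped-direction
#' canonical sets, each hierarchy-expanded; candidate edges come from
#' [lookup()] on each concrete pinned id; candidates are filtered by the
#' other query node's id/category constraints and by attribute
#' constraints; results are assembled per (subject node, object node) pair
#' with all parallel edges bound to the query edge, sorted for determinism.
#' Knowledge edges are reported in stored (canonical) orientation; node
#' bindings follow the query's orientation and carry `query_id` whenever a
#' match arose via equivalence or subclass expansion.
#'
#' @param qg Query graph (validated or raw; see [validate_query()]).
#' @param index A `kg_index`.
#' @param schema A `kg_schema`.
#' @param eqmap Optional `kg_eqmap` for concept equivalence.
#' @param closure Optional `kg_closure` for concept subclass chaining.
#' @param attribute_map Optional `trapi_attribute_map` controlling how
#'   properties are rendered as attributes in the answer.
#' @return A `kg_answers` object: `knowledge_nodes`, `knowledge_edges`,
#'   `results`.
#' @export
answer_query <- function(qg, index, schema, eqmap = NULL, closure = NULL,
                         attribute_map = NULL) {
  qg <- validate_query(qg, schema)
  ekey <- names(qg$edges)[1L]
  qe <- qg$edges[[1L]]
  skey <- qe$subject; okey <- qe$object
  qs <- qg$nodes[[skey]]; qo <- qg$nodes[[okey]]

  exp_s <- if (length(qs$ids)) expand_pinned_ids(qs$ids, eqmap, closure) else NULL
  exp_o <- if (length(qo$ids)) expand_pinned_ids(qo$ids, eqmap, closure) else NULL
  cat_s <- if (length(qs$categories)) {
    unique(unlist(lapply(qs$categories, descendants, schema = schema, kind = "category")))
  } else NULL
  cat_o <- if (length(qo$categories)) {
    unique(unlist(lapply(qo$categories, descendants, schema = schema, kind = "category")))
  } else NULL
  preds <- canonical_match_sets(schema, qe$predicates)

  # drive lookups from the pinned side with fewer concrete ids
  drive_subject <- if (is.null(exp_o)) TRUE
    else if (is.null(exp_s)) FALSE
    else length(exp_s) <= length(exp_o)

  candidates <- character()
  if (drive_subject) {
    for (c_id in names(exp_s)) {
      candidates <- c(
        candidates,
        lookup(index, c_id, "out", categories = cat_o, predicates = preds$forward),
        lookup(index, c_id, "in", categories = cat_o, predicates = preds$reverse)
      )
    }
  } else {
    for (c_id in names(exp_o)) {
      candidates <- c(
        candidates,
        lookup(index, c_id, "in", categories = cat_s, predicates = preds$forward),
        lookup(index, c_id, "out", categories = cat_s, predicates = preds$reverse)
      )
    }
  }
  candidates <- unique(candidates)
  if (!length(candidates)) {
    return(new_answerset(list(), node_payloads = node_payload_fn(index, attribute_map),
                         edge_payloads = edge_payload_fn(index, attribute_map),
                         skey = skey, okey = okey, ekey = ekey))
  }
  cand <- index$edges[data.table::J(candidates), on = "id"]
  cand <- apply_attribute_constraints(cand, qe$attribute_constraints)

  # ids and categories on the same qnode combine conjunctively
  node_ok <- function(node, exp, cats) {
    if (!is.null(exp) && !node %in% names(exp)) return(FALSE)
    if (!is.null(cats) && !any(index$category_of[[node]] %in% cats)) return(FALSE)
    TRUE
  }
  matches <- list()
  if (nrow(cand)) {
    for (i in seq_len(nrow(cand))) {
      s <- cand$subject[i]; o <- cand$object[i]; p <- cand$predicate[i]
      # forward reading: query subject corresponds to stored subject
      if ((p %in% preds$forward) && node_ok(s, exp_s, cat_s) && node_ok(o, exp_o, cat_o)) {
        matches[[length(matches) + 1L]] <- list(edge = cand$id[i], s_node = s, o_node = o)
      }
      # reverse reading: query subject corresponds to stored object
      # (duplicate (pair, edge) matches collapse during result grouping)
      if ((p %in% preds$reverse) && node_ok(o, exp_s, cat_s) && node_ok(s, exp_o, cat_o)) {
        matches[[length(matches) + 1L]] <- list(edge = cand$id[i], s_node = o, o_node = s)
      }
    }
  }
  new_answerset(matches,
                node_payloads = node_payload_fn(index, attribute_map),
                edge_payloads = edge_payload_fn(index, attribute_map),
                skey = skey, okey = okey, ekey = ekey,
                exp_s = exp_s, exp_o = exp_o)
}

# --- shared answer assembly (used by the engine and the brute-force oracle) --

node_payload_fn <- function(index, attribute_map) {
  function(node_id) {
    row <- index$nodes[data.table::J(node_id), on = "id"]
    list(
      name = if (is.na(row$name[1L])) NULL else row$name[1L],
      categories = as.list(row$categories[[1L]]),
      attributes = render_attributes(row$properties[[1L]], attribute_map)
    )
  }
}

edge_payload_fn <- function(index, attribute_map) {
  function(edge_id) {
    row <- index$edges[data.table::J(edge_id), on = "id"]
    list(
      subject = row$subject[1L],
      predicate = row$predicate[1L],
      object = row$object[1L],
      sources = if (is.na(row$primary_knowledge_source[1L])) list() else list(
        list(resource_id = row$primary_knowledge_source[1L],
             resource_role = "primary_knowledge_source")
      ),
      attributes = render_attributes(row$properties[[1L]], attribute_map)
    )
  }
}

render_attributes <- function(properties, attribute_map) {
  if (!length(properties)) return(list())
  props <- properties[setdiff(names(properties), "merged_values")]
  lapply(seq_along(props), function(i) {
    name <- names(props)[i]
    desc <- attribute_map[[name]]
    if (!is.null(desc)) {
      out <- list(
        attribute_type_id = desc$attribute_type_id %||% "biolink:Attribute",
        original_attribute_name = name,
        value = props[[i]]
      )
      if (!is.null(desc$value_type)) out$value_type_id <- desc$value_type
      out
    } else {
      list(attribute_type_id = "biolink:Attribute",
           original_attribute_name = name,
           value = props[[i]])
    }
  })
}

# matches: list of (edge, s_node, o_node); grouped into one result per
# (s_node, o_node) pair, deterministically sorted
new_answerset <- function(matches, node_payloads, edge_payloads,
                          skey, okey, ekey, exp_s = NULL, exp_o = NULL) {
  if (!length(matches)) {
    return(structure(
      list(knowledge_nodes = list(), knowledge_edges = list(), results = list()),
      class = "kg_answers"
    ))
  }
  s_nodes <- unname(vapply(matches, function(m) unname(m$s_node), character(1)))
  o_nodes <- unname(vapply(matches, function(m) unname(m$o_node), character(1)))
  eids <- unname(vapply(matches, function(m) unname(m$edge), character(1)))
  pair <- paste(s_nodes, o_nodes, sep = "\x1f")
  groups <- split(seq_along(matches), pair)
  ord <- order(names(groups))
  groups <- groups[ord]

  binding <- function(node, exp) {
    b <- list(id = node)
    if (!is.null(exp)) {
      qid <- unname(exp[node])
      if (!is.na(qid) && qid != node) b$query_id <- qid
    }
    b
  }
  results <- lapply(groups, function(ix) {
    s <- s_nodes[ix[1L]]; o <- o_nodes[ix[1L]]
    res <- list(node_bindings = list(), edge_bindings = list())
    res$node_bindings[[skey]] <- list(binding(s, exp_s))
    res$node_bindings[[okey]] <- list(binding(o, exp_o))
    res$edge_bindings[[ekey]] <- lapply(sort(unique(eids[ix])), function(e) list(id = e))
    res
  })
  names(results) <- NULL
  all_nodes <- sort(unique(c(s_nodes, o_nodes)))
  all_edges <- sort(unique(eids))
  structure(
    list(
      knowledge_nodes = stats::setNames(lapply(all_nodes, node_payloads), all_nodes),
      knowledge_edges = stats::setNames(lapply(all_edges, edge_payloads), all_edges),
      results = results
    ),
    class = "kg_answers"
  )
}

#' @export
print.kg_answers <- function(x, ...) {
  cat(sprintf("<kg_answers> %d results, %d knowledge nodes, %d knowledge edges\n",
              length(x$results), length(x$knowledge_nodes), length(x$knowledge_edges)))
  invisible(x)
}

#' Knowledge-edge ids of an answer set
#'
#' Convenience accessor: the sorted set of matched knowledge-edge ids.
#' @param answers A `kg_answers`.
#' @return Character vector.
#' @export
answer_edge_ids <- function(answers) {
  ids <- names(answers$knowledge_edges)
  if (is.null(ids)) character() else sort(unique(ids))
}

#' Render an answer set as a TRAPI-style message
#'
#' @param answers A `kg_answers`.
#' @param qg The (normalized) query graph that produced it.
#' @return A list shaped as `{message: {query_graph, knowledge_graph:
#'   {nodes, edges}, results}}`, ready for JSON serialization.
#' @export
as_trapi_message <- function(answers, qg) {
  results <- lapply(answers$results, function(r) {
    list(
      node_bindings = r$node_bindings,
      analyses = list(list(edge_bindings = r$edge_bindings))
    )
  })
  list(message = list(
    query_graph = unclass(qg),
    knowledge_graph = list(
      nodes = answers$knowledge_nodes,
      edges = answers$knowledge_edges
    ),
    results = results
  ))
}
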