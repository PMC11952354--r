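#' Specification for a synthetic knowledge graph
#'
#' Describes a randomly generated KGX graph with controlled semantic
#' structure, used to exercise every reasoning behavior of the engine:
#' symmetric-predicate edges, edges asserted via the non-canonical inverse
#' predicate, multi-member concept equivalence clusters, embedded
#' `subclass_of` chains, and multi-category nodes. Generation is
#' deterministic given `seed`.
#'
#' @param n_nodes Number of nodes.
#' @param n_edges Number of random (non-planted) edges.
#' @param seed Random seed.
#' @param schema A `kg_schema`; defaults to the demo schema shipped with
#'   the package.
#' @param p_symmetric Fraction of random edges drawn with a symmetric
#'   predicate.
#' @param p_inverse_asserted Fraction of canonical-predicate edges asserted
#'   via their inverse (subject/object swapped, inverse predicate).
#' @param n_equiv_clusters Number of multi-member equivalence clusters
#'   planted via shared `equivalent_identifiers` aliases.
#' @param subclass_chain_lengths Integer vector: for each entry k, a chain
#'   of k concepts linked child-`subclass_of`-parent is embedded, and every
#'   chain concept receives one "marker" edge so apex queries can recover
#'   the whole chain.
#' @param p_multi_category Fraction of nodes given a second category.
#' @return A `kg_fixture_spec`.
#' @export
fixture_spec <- function(n_nodes = 120L, n_edges = 400L, seed = 1L,
                         schema = demo_schema(),
                         p_symmetric = 0.2, p_inverse_asserted = 0.25,
                         n_equiv_clusters = 4L, subclass_chain_lengths = c(3L, 4L),
                         p_multi_category = 0.15) {
  probs <- c(p_symmetric, p_inverse_asserted, p_multi_category)
  if (any(probs < 0 | probs > 1)) abort_spec("probabilities must lie in [0, 1]")
  if (n_nodes < 1L || n_edges < 0L || n_equiv_clusters < 0L) {
    abort_spec("counts must be non-negative (and n_nodes >= 1)")
  }
  if (length(subclass_chain_lengths) && any(subclass_chain_lengths < 2L)) {
    abort_spec("subclass chains need at least 2 concepts")
  }
  if (sum(subclass_chain_lengths) + 3L * n_equiv_clusters > n_nodes) {
    abort_spec(sprintf(
      "infeasible spec: %d nodes cannot host chains totalling %d concepts plus %d clusters",
      n_nodes, sum(subclass_chain_lengths), n_equiv_clusters
    ))
  }
  structure(list(
    n_nodes = as.integer(n_nodes), n_edges = as.integer(n_edges),
    seed = as.integer(seed), schema = schema,
    p_symmetric = p_symmetric, p_inverse_asserted = p_inverse_asserted,
    n_equiv_clusters = as.integer(n_equiv_clusters),
    subclass_chain_lengths = as.integer(subclass_chain_lengths),
    p_multi_category = p_multi_category
  ), class = "kg_fixture_spec")
}

#' Demo schema shipped with the package
#'
#' Ten categories (rooted at `NamedThing`) and nine predicates (rooted at
#' `related_to`), including two symmetric predicates and two canonical
#' inverse pairs (`treats`/`treated_by`, `regulates`/`regulated_by`).
#' @return A `kg_schema`.
#' @export
demo_schema <- function() {
  load_schema(system.file("extdata", "demo_schema.yaml", package = "kghop"))
}

with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

FIXTURE_LEAF_PREFIX <- c(
  Drug = "DRUG", SmallMolecule = "CHEM", Gene = "GENE",
  Protein = "PROT", Disease = "MONDO", PhenotypicFeature = "HP"
)

#' Generate a synthetic KGX knowledge graph
#'
#' Emits the graph described by a [fixture_spec()] in both KGX dialects
#' (TSV and JSON Lines) from a single in-memory build, together with a
#' manifest recording every planted structure (equivalence clusters,
#' subclass chains with their marker edges, inverse-asserted edge ids,
#' symmetric edge ids). Byte-identical output for a given seed.
#'
#' @param spec A `kg_fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return List with `graph` (the in-memory [kg_graph()]), `dir`, `files`
#'   (paths of the four KGX files and the manifest) and `manifest`.
#' @export
generate_kg <- function(spec, dir = tempfile("kgfixture")) {
  stopifnot(inherits(spec, "kg_fixture_spec"))
  built <- with_local_seed(spec$seed, build_fixture_graph(spec))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- list(
    nodes_tsv = file.path(dir, "nodes.tsv"),
    edges_tsv = file.path(dir, "edges.tsv"),
    nodes_jsonl = file.path(dir, "nodes.jsonl"),
    edges_jsonl = file.path(dir, "edges.jsonl"),
    manifest = file.path(dir, "manifest.json")
  )
  write_kgx_tsv(built$graph, files$nodes_tsv, files$edges_tsv)
  write_kgx_jsonlines(built$graph, files$nodes_jsonl, files$edges_jsonl)
  writeLines(as.character(jsonlite::toJSON(built$manifest, auto_unbox = TRUE, pretty = TRUE)),
             files$manifest)
  list(graph = built$graph, dir = dir, files = files, manifest = built$manifest)
}

build_fixture_graph <- function(spec) {
  schema <- spec$schema
  leaves <- intersect(names(FIXTURE_LEAF_PREFIX), names(schema$categories))
  n <- spec$n_nodes

  chain_sizes <- spec$subclass_chain_lengths
  n_chain_nodes <- sum(chain_sizes)
  primary <- character(n)
  # chain concepts are diseases: subclass chains among disease terms
  primary[seq_len(n_chain_nodes)] <- "Disease"
  if (n > n_chain_nodes) {
    primary[(n_chain_nodes + 1L):n] <- sample(leaves, n - n_chain_nodes, replace = TRUE)
  }
  ids <- sprintf("%s:%05d", FIXTURE_LEAF_PREFIX[primary], seq_len(n))
  categories <- lapply(seq_len(n), function(i) {
    cats <- primary[i]
    if (stats::runif(1) < spec$p_multi_category) {
      extra <- sample(setdiff(names(schema$categories),
                              c(cats, schema$category_root)), 1L)
      cats <- c(cats, extra)
    }
    cats
  })

  equivalent_identifiers <- replicate(n, character(), simplify = FALSE)
  pool <- setdiff(seq_len(n), seq_len(n_chain_nodes))
  clusters <- list()
  for (k in seq_len(spec$n_equiv_clusters)) {
    size <- sample(2:3, 1L)
    members <- sort(pool[sample.int(length(pool), size)])
    pool <- setdiff(pool, members)
    alias <- sprintf("EQV:C%03d", k)
    for (m in members) {
      equivalent_identifiers[[m]] <- c(ids[m], alias)
    }
    clusters[[k]] <- list(alias = alias, members = ids[members])
  }

  nodes <- data.table::data.table(
    id = ids,
    name = sprintf("concept %05d", seq_len(n)),
    categories = categories,
    equivalent_identifiers = equivalent_identifiers,
    properties = replicate(n, list(), simplify = FALSE)
  )

  sym_preds <- c("interacts_with", "associated_with")
  canon_base <- c("treats", "regulates", "affects")
  inverse_of <- c(treats = "treated_by", regulates = "regulated_by")
  sources <- c("infores:drugbank", "infores:semmeddb", "infores:ctd")

  es <- character(); ep <- character(); eo <- character()
  eprops <- list(); epks <- character()
  sym_rows <- integer(); inv_rows <- integer()
  add_edge <- function(s, p, o, pks, props) {
    es[[length(es) + 1L]] <<- s
    ep[[length(ep) + 1L]] <<- p
    eo[[length(eo) + 1L]] <<- o
    epks[[length(epks) + 1L]] <<- pks
    eprops[[length(eprops) + 1L]] <<- props
    length(es)
  }
  random_props <- function() {
    props <- list()
    if (stats::runif(1) < 0.5) {
      props$publications <- sprintf("PMID:%d", sample.int(99999L, sample(1:3, 1L)))
    }
    if (stats::runif(1) < 0.4) {
      props$score <- sprintf("%.3f", stats::runif(1))
    }
    props
  }

  chains <- list()
  offset <- 0L
  drug_pool <- which(primary %in% c("Drug", "SmallMolecule"))
  if (!length(drug_pool)) drug_pool <- seq_len(n)
  for (L in chain_sizes) {
    members <- ids[(offset + 1L):(offset + L)]
    offset <- offset + L
    chain_rows <- integer(); marker_rows <- integer()
    for (j in seq_len(L - 1L)) {
      chain_rows <- c(chain_rows, add_edge(members[j + 1L], "subclass_of", members[j],
                                           "infores:mondo", list()))
    }
    for (m in members) {
      drug <- ids[drug_pool[sample.int(length(drug_pool), 1L)]]
      pks <- sample(sources, 1L)
      if (stats::runif(1) < spec$p_inverse_asserted) {
        r <- add_edge(m, "treated_by", drug, pks, random_props())
        inv_rows <- c(inv_rows, r)
      } else {
        r <- add_edge(drug, "treats", m, pks, random_props())
      }
      marker_rows <- c(marker_rows, r)
    }
    chains[[length(chains) + 1L]] <- list(
      apex = members[1L], nodes = members,
      chain_rows = chain_rows, marker_rows = marker_rows
    )
  }

  for (k in seq_len(spec$n_edges)) {
    pair <- sample.int(n, 2L)
    s <- ids[pair[1L]]; o <- ids[pair[2L]]
    pks <- sample(sources, 1L)
    if (stats::runif(1) < spec$p_symmetric) {
      r <- add_edge(s, sample(sym_preds, 1L), o, pks, random_props())
      sym_rows <- c(sym_rows, r)
    } else {
      base <- sample(canon_base, 1L)
      if (base %in% names(inverse_of) && stats::runif(1) < spec$p_inverse_asserted) {
        r <- add_edge(o, inverse_of[[base]], s, pks, random_props())
        inv_rows <- c(inv_rows, r)
      } else {
        r <- add_edge(s, base, o, pks, random_props())
      }
    }
  }

  edge_ids <- sprintf("E%05d", seq_along(es))
  edges <- data.table::data.table(
    id = edge_ids, subject = es, predicate = ep, object = eo,
    primary_knowledge_source = epks, properties = eprops
  )
  graph <- kg_graph(nodes, edges, provenance = list(source = "synthetic", seed = spec$seed))
  manifest <- list(
    seed = spec$seed,
    n_nodes = n,
    n_edges = nrow(edges),
    equivalence_clusters = lapply(clusters, function(cl) {
      list(alias = cl$alias, members = cl$members)
    }),
    subclass_chains = lapply(chains, function(ch) list(
      apex = ch$apex, nodes = ch$nodes,
      subclass_edge_ids = edge_ids[ch$chain_rows],
      marker_edge_ids = edge_ids[ch$marker_rows]
    )),
    inverse_asserted_edge_ids = edge_ids[inv_rows],
    symmetric_edge_ids = edge_ids[sym_rows]
  )
  list(graph = graph, manifest = manifest)
}

#' Sample a random one-hop query
#'
#' Draws a valid one-hop query graph against a generated graph, biased
#' toward planted structures when a manifest is supplied (cluster members
#' and aliases, subclass-chain concepts), and mixing in category
#' constraints, hierarchy-ancestor and inverse predicates, both-pinned
#' queries, and attribute constraints. Deterministic given `seed`.
#'
#' @param graph A [kg_graph()].
#' @param schema A `kg_schema`.
#' @param seed Random seed.
#' @param manifest Optional manifest from [generate_kg()].
#' @return A query-graph list that passes [validate_query()].
#' @export
random_query <- function(graph, schema, seed, manifest = NULL) {
  if (!nrow(graph$nodes)) abort_spec("cannot sample a query against an empty graph")
  with_local_seed(seed, {
    node_ids <- graph$nodes$id
    planted <- if (!is.null(manifest)) {
      c(
        unlist(lapply(manifest$equivalence_clusters, function(cl) c(cl$alias, cl$members))),
        unlist(lapply(manifest$subclass_chains, `[[`, "nodes"))
      )
    } else character()
    pick_node <- function() {
      if (length(planted) && stats::runif(1) < 0.4) sample(planted, 1L)
      else sample(node_ids, 1L)
    }
    shape <- sample(c("single", "both_random", "both_edge"), 1L,
                    prob = c(0.72, 0.08, 0.20))
    if (shape == "both_edge" && nrow(graph$edges)) {
      e <- graph$edges[sample.int(nrow(graph$edges), 1L)]
      pin_s <- e$subject; pin_o <- e$object
      if (stats::runif(1) < 0.5) { tmp <- pin_s; pin_s <- pin_o; pin_o <- tmp }
    } else if (shape == "both_random") {
      pin_s <- pick_node(); pin_o <- pick_node()
    } else {
      pinned_subject <- stats::runif(1) < 0.5
      pin_s <- if (pinned_subject) pick_node() else NULL
      pin_o <- if (pinned_subject) NULL else pick_node()
    }
    n0 <- list(); n1 <- list()
    if (!is.null(pin_s)) n0$ids <- pin_s
    if (!is.null(pin_o)) n1$ids <- pin_o
    for (side in c("n0", "n1")) {
      open <- (side == "n0" && is.null(pin_s)) || (side == "n1" && is.null(pin_o))
      p_cat <- if (open) 0.45 else 0.10
      if (stats::runif(1) < p_cat) {
        cat <- sample(names(schema$categories), 1L)
        if (side == "n0") n0$categories <- cat else n1$categories <- cat
      }
    }
    qe <- list(subject = "n0", object = "n1")
    if (stats::runif(1) < 0.7) {
      qe$predicates <- sample(names(schema$predicates), sample(1:2, 1L))
    }
    if (stats::runif(1) < 0.25) {
      qe$attribute_constraints <- list(sample(list(
        list(name = "knowledge_source", operator = "==",
             value = sample(c("infores:drugbank", "infores:semmeddb", "infores:ctd"), 1L),
             negated = stats::runif(1) < 0.3),
        list(name = "publications", operator = "matches", value = "^PMID:"),
        list(name = "score", operator = sample(c(">", "<"), 1L), value = "0.5")
      ), 1L)[[1L]])
    }
    list(nodes = list(n0 = n0, n1 = n1), edges = list(e0 = qe))
  })
}

#' Brute-force one-hop query oracle
#'
#' Answers a one-hop query by a linear scan over the graph's edge list,
#' applying all five reasoning behaviors per edge, with no adjacency index:
#' every edge is expanded into its valid readings (as asserted; reversed
#' for symmetric predicates; via the inverse predicate for inverse pairs),
#' a reading's predicate matches the query if any of its schema ancestors
#' is among the query predicates, pinned ids expand through equivalence
#' representatives and subclass descendants, and open-node categories match
#' through each node category's ancestor set. Intended as an independent
#' check of [answer_query()] on small graphs (O(edges x expansions)).
#'
#' @param graph A [kg_graph()].
#' @param schema A `kg_schema`.
#' @param eqmap A `kg_eqmap` or `NULL`.
#' @param closure A `kg_closure` or `NULL`.
#' @param qg Query graph or TRAPI message.
#' @param attribute_map Optional attribute map for answer rendering.
#' @return A `kg_answers` semantically identical to the engine's.
#' @export
brute_force_answer <- function(graph, schema, eqmap, closure, qg,
                               attribute_map = NULL) {
  qg <- validate_query(qg, schema)
  qe <- qg$edges[[1L]]
  qs <- qg$nodes[[qe$subject]]; qo <- qg$nodes[[qe$object]]
  edges <- graph$edges
  node_ids <- graph$nodes$id

  # mirror the build-time skip rules: unknown predicate or missing endpoint
  keep <- edges$predicate %in% names(schema$predicates) &
    edges$subject %in% node_ids & edges$object %in% node_ids
  edges <- edges[keep]

  # effective categories: schema-known, with the category root as fallback
  node_cats <- lapply(graph$nodes$categories, function(cc) {
    cc <- intersect(cc, names(schema$categories))
    if (!length(cc)) schema$category_root else cc
  })
  names(node_cats) <- node_ids

  # all readings of every edge
  sym <- vapply(edges$predicate, function(p) isTRUE(schema$predicates[[p]]$symmetric),
                logical(1))
  inv <- vapply(edges$predicate, function(p) schema$predicates[[p]]$inverse, character(1))
  has_inv <- !is.na(inv)
  r_s <- c(edges$subject, edges$object[sym], edges$object[has_inv])
  r_p <- c(edges$predicate, edges$predicate[sym], inv[has_inv])
  r_o <- c(edges$object, edges$subject[sym], edges$subject[has_inv])
  r_row <- c(seq_len(nrow(edges)), which(sym), which(has_inv))

  # predicate filter: a reading matches a query predicate when that query
  # predicate is among the reading predicate's ancestors. Query predicates
  # that are symmetric, or the predicate root (no constraint at all), are
  # direction-free: their readings additionally match with the query
  # orientation reversed.
  qpreds <- if (length(qe$predicates)) qe$predicates else schema$predicate_root
  dfree <- qpreds[vapply(qpreds, function(p) {
    isTRUE(schema$predicates[[p]]$symmetric) || identical(p, schema$predicate_root)
  }, logical(1))]
  all_preds <- names(schema$predicates)
  allowed_fwd <- all_preds[vapply(all_preds, function(p) {
    any(ancestors(schema, p, "predicate") %in% qpreds)
  }, logical(1))]
  allowed_rev <- all_preds[vapply(all_preds, function(p) {
    any(ancestors(schema, p, "predicate") %in% dfree)
  }, logical(1))]
  pred_ok <- r_p %in% allowed_fwd
  pred_ok_rev <- r_p %in% allowed_rev

  # oracle's own id expansion: representative, then subclass descendants
  expand <- function(query_ids) {
    desc_of <- function(x) {
      if (!is.null(closure) && !is.null(closure$descendants_of[[x]])) {
        closure$descendants_of[[x]]
      } else x
    }
    out <- character()
    for (qid in query_ids) {
      rep_id <- if (!is.null(eqmap) && qid %in% names(eqmap$representative)) {
        unname(eqmap$representative[[qid]])
      } else qid
      concrete <- unique(c(desc_of(qid), desc_of(rep_id)))
      fresh <- setdiff(concrete, names(out))
      out[fresh] <- qid
    }
    out
  }
  exp_s <- if (length(qs$ids)) expand(qs$ids) else NULL
  exp_o <- if (length(qo$ids)) expand(qo$ids) else NULL

  side_ok <- function(nodes_vec, pin_exp, categories) {
    ok <- rep(TRUE, length(nodes_vec))
    if (!is.null(pin_exp)) ok <- nodes_vec %in% names(pin_exp)
    if (length(categories)) {  # conjunctive with any id pin
      ok <- ok & vapply(nodes_vec, function(nd) {
        any(unlist(lapply(node_cats[[nd]], ancestors, schema = schema,
                          kind = "category")) %in% categories)
      }, logical(1))
    }
    ok
  }
  ok <- pred_ok & side_ok(r_s, exp_s, qs$categories) & side_ok(r_o, exp_o, qo$categories)
  # reversed-orientation matches for direction-free query predicates
  ok_rev <- pred_ok_rev & side_ok(r_o, exp_s, qs$categories) &
    side_ok(r_s, exp_o, qo$categories)

  # independent per-reading attribute-constraint evaluation
  if (length(qe$attribute_constraints) && any(ok | ok_rev)) {
    for (i in which(ok | ok_rev)) {
      row <- r_row[i]
      props <- edges$properties[[row]]
      pks <- edges$primary_knowledge_source[row]
      for (ac in qe$attribute_constraints) {
        vals <- if (ac$name %in% c("knowledge_source", "primary_knowledge_source")) {
          if (is.na(pks)) NULL else pks
        } else if (ac$name %in% names(props)) props[[ac$name]] else NULL
        hit <- if (is.null(vals) || !length(vals)) FALSE else {
          v <- as.character(unlist(vals)); cv <- as.character(unlist(ac$value))
          switch(ac$operator,
            "==" = any(v %in% cv),
            ">" = if (!anyNA(suppressWarnings(as.numeric(v))) &&
                      !is.na(suppressWarnings(as.numeric(cv[1L])))) {
              any(as.numeric(v) > as.numeric(cv[1L]))
            } else any(v > cv[1L]),
            "<" = if (!anyNA(suppressWarnings(as.numeric(v))) &&
                      !is.na(suppressWarnings(as.numeric(cv[1L])))) {
              any(as.numeric(v) < as.numeric(cv[1L]))
            } else any(v < cv[1L]),
            "matches" = tryCatch(
              suppressWarnings(any(vapply(cv, function(pt) any(grepl(pt, v)), logical(1)))),
              error = function(e) abort_constraint(conditionMessage(e))
            )
          )
        }
        if (isTRUE(ac$negated)) hit <- !hit
        if (!hit) { ok[i] <- FALSE; ok_rev[i] <- FALSE; break }
      }
    }
  }

  matches <- c(
    lapply(which(ok), function(i) {
      list(edge = edges$id[r_row[i]], s_node = r_s[i], o_node = r_o[i])
    }),
    lapply(which(ok_rev), function(i) {
      list(edge = edges$id[r_row[i]], s_node = r_o[i], o_node = r_s[i])
    })
  )
  new_answerset(
    matches,
    node_payloads = oracle_node_payload_fn(graph, attribute_map),
    edge_payloads = oracle_edge_payload_fn(graph, schema, attribute_map),
    skey = qe$subject, okey = qe$object, ekey = names(qg$edges)[1L],
    exp_s = exp_s, exp_o = exp_o
  )
}

oracle_node_payload_fn <- function(graph, attribute_map) {
  idx <- stats::setNames(seq_len(nrow(graph$nodes)), graph$nodes$id)
  function(id) {
    i <- idx[[id]]
    list(
      name = if (is.na(graph$nodes$name[i])) NULL else graph$nodes$name[i],
      categories = as.list(graph$nodes$categories[[i]]),
      attributes = render_attributes(graph$nodes$properties[[i]], attribute_map)
    )
  }
}

# payloads report canonical orientation, like the engine's stored edges
oracle_edge_payload_fn <- function(graph, schema, attribute_map) {
  idx <- stats::setNames(seq_len(nrow(graph$edges)), graph$edges$id)
  function(id) {
    i <- idx[[id]]
    cf <- canonical_form(schema, graph$edges$predicate[i])
    s <- graph$edges$subject[i]; o <- graph$edges$object[i]
    if (cf$flipped) { tmp <- s; s <- o; o <- tmp }
    pks <- graph$edges$primary_knowledge_source[i]
    list(
      subject = s,
      predicate = cf$predicate,
      object = o,
      sources = if (is.na(pks)) list() else list(
        list(resource_id = pks, resource_role = "primary_knowledge_source")
      ),
      attributes = render_attributes(graph$edges$properties[[i]], attribute_map)
    )
  }
}
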