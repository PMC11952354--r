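#' Build the in-memory adjacency index
#'
#' The engine's core data structure is a nested adjacency dictionary: each
#' node maps to its neighbors, organized by direction (`out`/`in`), by the
#' most-specific categories of the neighbor, and by the canonical predicate
#' of the connecting edge, down to sets of edge ids. Together with the
#' schema's precomputed hierarchy closures this gives constant-time lookups
#' at query time.
#'
#' Build-time normalization:
#' * every edge's predicate is rewritten to its [canonical_form()]; when the
#'   asserted predicate is the non-canonical member of an inverse pair the
#'   stored subject/object are swapped and the edge keeps a `flipped` flag
#'   recording its original orientation;
#' * symmetric-predicate edges are posted under both endpoints' `out` (and
#'   `in`) direction so they are reachable from either side;
#' * nodes with no (schema-known) category are assigned the schema's
#'   category root, with a warning;
#' * index keys use each node's *most-specific* categories (categories with
#'   a descendant also present on the node are dropped from keys; the full
#'   list stays on the node record) — the query layer expands query
#'   categories/predicates to descendant sets before lookup;
#' * edges referencing missing nodes, or carrying predicates unknown to the
#'   schema, are skipped and counted.
#'
#' Build statistics are in `index$stats` (`n_nodes`, `n_edges`,
#' `n_edges_flipped`, `n_edges_skipped_missing_endpoint`,
#' `n_edges_skipped_unknown_predicate`).
#'
#' @param graph A [kg_graph()].
#' @param schema A `kg_schema`.
#' @return A `kg_index`.
#' @export
build_index <- function(graph, schema) {
  nodes <- data.table::copy(graph$nodes)
  if (nrow(nodes)) data.table::setkey(nodes, id)  # sort once, before any column is aliased
  n_uncategorized <- 0L
  if (nrow(nodes)) {
    known <- names(schema$categories)
    cats_known <- lapply(nodes$categories, function(cc) intersect(cc, known))
    n_uncategorized <- sum(lengths(cats_known) == 0L)
    if (n_uncategorized > 0L) {
      warning(sprintf(
        "%d node(s) without a schema-known category; assigned category root '%s'",
        n_uncategorized, schema$category_root
      ), call. = FALSE)
      cats_known[lengths(cats_known) == 0L] <- list(schema$category_root)
    }
    ms_cats <- lapply(cats_known, function(cc) most_specific_categories(schema, cc))
  } else {
    ms_cats <- list()
  }
  category_of <- stats::setNames(ms_cats, nodes$id)

  edges <- graph$edges
  n_flipped <- 0L; n_missing <- 0L; n_unknown_pred <- 0L
  stored <- empty_stored_edges()
  if (nrow(edges)) {
    known_pred <- edges$predicate %in% names(schema$predicates)
    n_unknown_pred <- sum(!known_pred)
    endpoint_ok <- edges$subject %in% nodes$id & edges$object %in% nodes$id
    n_missing <- sum(known_pred & !endpoint_ok)
    keep <- known_pred & endpoint_ok
    edges <- edges[keep]
    if (nrow(edges)) {
      upreds <- unique(edges$predicate)
      cf <- lapply(upreds, function(p) canonical_form(schema, p))
      canon <- stats::setNames(vapply(cf, `[[`, character(1), "predicate"), upreds)
      flip <- stats::setNames(vapply(cf, `[[`, logical(1), "flipped"), upreds)
      flipped <- unname(flip[edges$predicate])
      n_flipped <- sum(flipped)
      stored <- data.table::data.table(
        id = edges$id,
        subject = ifelse(flipped, edges$object, edges$subject),
        predicate = unname(canon[edges$predicate]),
        object = ifelse(flipped, edges$subject, edges$object),
        primary_knowledge_source = edges$primary_knowledge_source,
        flipped = flipped,
        properties = edges$properties
      )
    }
  }

  adjacency <- new.env(parent = emptyenv(), size = max(16L, nrow(nodes)))
  if (nrow(stored)) {
    sym <- vapply(stored$predicate, function(p) is_symmetric_predicate(schema, p), logical(1))
    post <- function(node, dir, neighbor, pred, eid) {
      entry <- adjacency[[node]]
      if (is.null(entry)) entry <- list(out = list(), `in` = list())
      for (cat in category_of[[neighbor]]) {
        entry[[dir]][[cat]][[pred]] <- c(entry[[dir]][[cat]][[pred]], eid)
      }
      adjacency[[node]] <- entry
    }
    for (i in seq_len(nrow(stored))) {
      s <- stored$subject[i]; o <- stored$object[i]
      p <- stored$predicate[i]; eid <- stored$id[i]
      post(s, "out", o, p, eid)
      post(o, "in", s, p, eid)
      if (sym[i] && s != o) {
        post(o, "out", s, p, eid)
        post(s, "in", o, p, eid)
      }
    }
  }
  edges_by_id <- stored
  if (nrow(edges_by_id)) data.table::setkey(edges_by_id, id)
  structure(list(
    adjacency = adjacency,
    edges = edges_by_id,
    nodes = nodes,
    category_of = category_of,
    stats = list(
      n_nodes = nrow(nodes),
      n_edges = nrow(stored),
      n_edges_flipped = as.integer(n_flipped),
      n_edges_skipped_missing_endpoint = as.integer(n_missing),
      n_edges_skipped_unknown_predicate = as.integer(n_unknown_pred),
      n_nodes_assigned_root_category = as.integer(n_uncategorized)
    )
  ), class = "kg_index")
}

empty_stored_edges <- function() {
  data.table::data.table(
    id = character(), subject = character(), predicate = character(),
    object = character(), primary_knowledge_source = character(),
    flipped = logical(), properties = list()
  )
}

#' @export
print.kg_index <- function(x, ...) {
  cat(sprintf("<kg_index> %d nodes, %d stored edges (%d flipped to canonical orientation)\n",
              x$stats$n_nodes, x$stats$n_edges, x$stats$n_edges_flipped))
  invisible(x)
}

# drop categories that have a strict descendant also present in the set
most_specific_categories <- function(schema, cats) {
  cats <- unique(cats)
  if (length(cats) <= 1L) return(cats)
  keep <- vapply(cats, function(c1) {
    !any(setdiff(descendants(schema, c1, "category"), c1) %in% cats)
  }, logical(1))
  cats[keep]
}

#' Constant-time edge lookup
#'
#' Returns the union of the index's posting sets for the requested keys.
#' `categories` filters on the *neighbor's* most-specific categories and
#' `predicates` on canonical predicates; both are expected to already be
#' closed over the schema hierarchy by the caller (the query engine does
#' this). Omitted filters mean "all"; an unknown node is not an error and
#' returns the empty set.
#'
#' @param index A `kg_index`.
#' @param node Node CURIE.
#' @param direction `"out"`, `"in"` or `"any"`.
#' @param categories Optional neighbor-category filter (character vector).
#' @param predicates Optional canonical-predicate filter (character vector).
#' @return Character vector of edge ids (unordered, unique).
#' @export
lookup <- function(index, node, direction = c("any", "out", "in"),
                   categories = NULL, predicates = NULL) {
  direction <- match.arg(direction)
  entry <- index$adjacency[[node]]
  if (is.null(entry)) return(character())
  dirs <- if (direction == "any") c("out", "in") else direction
  out <- character()
  for (d in dirs) {
    sub <- entry[[d]]
    cats <- if (is.null(categories)) names(sub) else intersect(names(sub), categories)
    for (cat in cats) {
      bypred <- sub[[cat]]
      preds <- if (is.null(predicates)) names(bypred) else intersect(names(bypred), predicates)
      for (p in preds) out <- c(out, bypred[[p]])
    }
  }
  unique(out)
}

#' Transitive closure of concept subclass relations
#'
#' Chains `subclass_of`-style edges present in the graph (and/or an external
#' pair list) so that a concept's descendant set contains every concept
#' reachable through child-of links, up to `max_depth` steps. The closure is
#' reflexive. Cycles are detected, reported with a warning, and broken by
#' the visited-set traversal — members of a cycle become mutual descendants.
#'
#' @param graph A [kg_graph()].
#' @param subclass_predicates Predicate labels whose edges assert
#'   child-`subclass_of`-parent relations (default `"subclass_of"`).
#' @param external_pairs Optional two-column object (child, parent) of CURIE
#'   pairs from a user-specified external source.
#' @param max_depth Maximum chaining depth (`Inf` = unlimited).
#' @return A `kg_closure`: list with `descendants_of` (named list,
#'   concept -> reflexive descendant set; concepts with no subclass
#'   relations are omitted and implicitly map to themselves) and `source`.
#' @export
compute_subclass_closure <- function(graph, subclass_predicates = "subclass_of",
                                     external_pairs = NULL, max_depth = Inf) {
  subclass_predicates <- strip_label_prefix(subclass_predicates)
  child <- character(); parent <- character()
  if (nrow(graph$edges)) {
    sel <- graph$edges$predicate %in% subclass_predicates
    child <- graph$edges$subject[sel]
    parent <- graph$edges$object[sel]
  }
  if (!is.null(external_pairs)) {
    ep <- as.matrix(external_pairs)[, 1:2, drop = FALSE]
    child <- c(child, ep[, 1L])
    parent <- c(parent, ep[, 2L])
  }
  concepts <- unique(c(child, parent))
  children_of <- split(child, factor(parent, levels = concepts))
  descendants_of <- stats::setNames(vector("list", length(concepts)), concepts)
  cycle_seen <- FALSE
  for (x in concepts) {
    visited <- character()
    frontier <- x
    depth <- 0
    while (length(frontier) && depth < max_depth) {
      nxt <- unique(unlist(children_of[intersect(frontier, concepts)], use.names = FALSE))
      if (!cycle_seen && x %in% nxt) cycle_seen <- TRUE
      nxt <- setdiff(nxt, c(visited, x))
      visited <- c(visited, nxt)
      frontier <- nxt
      depth <- depth + 1
    }
    descendants_of[[x]] <- c(x, visited)
  }
  if (cycle_seen) {
    warning("subclass relations contain a cycle; members treated as mutual descendants",
            call. = FALSE)
  }
  structure(
    list(
      descendants_of = descendants_of,
      source = list(predicates = subclass_predicates,
                    n_external_pairs = if (is.null(external_pairs)) 0L else nrow(as.matrix(external_pairs)),
                    max_depth = max_depth)
    ),
    class = "kg_closure"
  )
}

# reflexive descendant set of a concept (identity for unknown concepts)
closure_descendants <- function(closure, id) {
  if (is.null(closure)) return(id)
  res <- closure$descendants_of[[id]]
  if (is.null(res)) id else res
}

#' Persist and restore an index snapshot
#'
#' `save_index()` writes the adjacency index and subclass closure to a
#' single versioned snapshot file; `load_index()` restores them such that
#' every [lookup()] gives identical results. The snapshot is a run-time
#' artifact (RDS serialization with a format-version field), not an
#' interchange format.
#'
#' @param index A `kg_index`.
#' @param closure A `kg_closure` (or `NULL`).
#' @param path Snapshot file path.
#' @return `load_index()` returns `list(index = , closure = )`.
#' @export
save_index <- function(index, closure, path) {
  payload <- list(
    format = "kghop-index-snapshot",
    format_version = 1L,
    index = list(
      adjacency = as.list(index$adjacency, all.names = TRUE),
      edges = index$edges,
      nodes = index$nodes,
      category_of = index$category_of,
      stats = index$stats
    ),
    closure = closure
  )
  ok <- tryCatch({ saveRDS(payload, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) {
    kghop_abort(sprintf("cannot write snapshot '%s': %s", path, conditionMessage(ok)),
                "kghop_io_error")
  }
  invisible(NULL)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) abort_load(sprintf("snapshot file not found: '%s'", path))
  payload <- tryCatch(readRDS(path), error = function(e) {
    abort_load(sprintf("cannot read snapshot '%s': %s", path, conditionMessage(e)))
  })
  if (!is.list(payload) || !identical(payload$format, "kghop-index-snapshot")) {
    abort_load(sprintf("'%s' is not an index snapshot", path))
  }
  if (!identical(payload$format_version, 1L)) {
    abort_load(sprintf("unsupported snapshot format version: %s", payload$format_version))
  }
  adjacency <- new.env(parent = emptyenv())
  if (length(payload$index$adjacency)) {
    adjacency <- list2env(payload$index$adjacency, envir = adjacency)
  }
  index <- structure(list(
    adjacency = adjacency,
    edges = payload$index$edges,
    nodes = payload$index$nodes,
    category_of = payload$index$category_of,
    stats = payload$index$stats
  ), class = "kg_index")
  if (nrow(index$edges)) data.table::setkey(index$edges, id)
  list(index = index, closure = payload$closure)
}
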