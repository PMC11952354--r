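#' Build the meta knowledge graph
#'
#' Summarizes which (subject category, predicate, object category) triples
#' the hosted graph can answer, for client-side query routing. One
#' meta-edge is produced per distinct triple of most-specific subject
#' category, canonical predicate, and most-specific object category over
#' stored edges; nodes carrying several most-specific categories contribute
#' the cross-product of their category pairs. Counts record how many stored
#' edges contribute to each triple (an extension over the bare TRAPI shape).
#' Meta-nodes map each observed category to the sorted CURIE prefixes (text
#' before the first colon) of nodes carrying it.
#'
#' @param index A `kg_index`.
#' @param schema A `kg_schema` (hierarchy context; meta-edges use asserted
#'   most-specific categories without roll-up, which stays recoverable
#'   through the schema).
#' @return A `kg_metakg`: list with `meta_nodes` (category ->
#'   `list(id_prefixes = ...)`) and `meta_edges` (`data.table` with
#'   `subject_category`, `predicate`, `object_category`, `count`).
#' @export
build_meta_kg <- function(index, schema) {
  meta_nodes <- list()
  if (nrow(index$nodes)) {
    prefixes <- sub(":.*$", "", index$nodes$id)
    for (i in seq_len(nrow(index$nodes))) {
      for (cat in index$category_of[[index$nodes$id[i]]]) {
        meta_nodes[[cat]] <- c(meta_nodes[[cat]], prefixes[i])
      }
    }
    meta_nodes <- lapply(meta_nodes, function(p) list(id_prefixes = sort(unique(p))))
    meta_nodes <- meta_nodes[order(names(meta_nodes))]
  }
  contrib <- meta_edge_contributions(index)
  meta_edges <- if (nrow(contrib)) {
    me <- contrib[, list(count = length(unique(id))),
                  by = c("subject_category", "predicate", "object_category")]
    data.table::setorder(me, subject_category, predicate, object_category)
    me
  } else {
    data.table::data.table(
      subject_category = character(), predicate = character(),
      object_category = character(), count = integer()
    )
  }
  structure(list(meta_nodes = meta_nodes, meta_edges = meta_edges),
            class = "kg_metakg")
}

# long table: one row per (stored edge, subject ms-category, object ms-category)
meta_edge_contributions <- function(index) {
  edges <- index$edges
  if (!nrow(edges)) {
    return(data.table::data.table(
      id = character(), subject = character(), predicate = character(),
      object = character(), subject_category = character(), object_category = character()
    ))
  }
  rows <- lapply(seq_len(nrow(edges)), function(i) {
    scats <- index$category_of[[edges$subject[i]]]
    ocats <- index$category_of[[edges$object[i]]]
    grid <- expand.grid(subject_category = scats, object_category = ocats,
                        stringsAsFactors = FALSE)
    data.table::data.table(
      id = edges$id[i], subject = edges$subject[i], predicate = edges$predicate[i],
      object = edges$object[i],
      subject_category = grid$subject_category, object_category = grid$object_category
    )
  })
  data.table::rbindlist(rows)
}

#' @export
print.kg_metakg <- function(x, ...) {
  cat(sprintf("<kg_metakg> %d meta-nodes, %d meta-edges\n",
              length(x$meta_nodes), nrow(x$meta_edges)))
  invisible(x)
}

#' Derive exemplar test triples
#'
#' One concrete exemplar edge per meta-edge, for smoke-testing a deployed
#' graph API: each triple records the meta-edge's categories and predicate
#' plus an actual stored edge's subject and object ids. The exemplar is
#' chosen deterministically as the lexicographically smallest
#' (subject id, object id, edge id) among contributing edges, so rebuilds
#' yield identical triples.
#'
#' @param index The `kg_index` the meta-KG was built from.
#' @param metakg The corresponding `kg_metakg`.
#' @return A `data.table` with columns `subject_category`, `predicate`,
#'   `object_category`, `subject_id`, `object_id`.
#' @export
build_test_triples <- function(index, metakg) {
  contrib <- meta_edge_contributions(index)
  if (!nrow(contrib)) {
    return(data.table::data.table(
      subject_category = character(), predicate = character(),
      object_category = character(), subject_id = character(), object_id = character()
    ))
  }
  data.table::setorder(contrib, subject_category, predicate, object_category,
                       subject, object, id)
  first <- contrib[, .SD[1L], by = c("subject_category", "predicate", "object_category")]
  out <- first[, c("subject_category", "predicate", "object_category", "subject", "object")]
  data.table::setnames(out, c("subject", "object"), c("subject_id", "object_id"))
  out
}
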