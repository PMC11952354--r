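#' Build a concept-equivalence map
#'
#' Clusters CURIEs that denote the same real-world concept. Evidence comes
#' from the graph itself (`provider = "file"`: each node's
#' `equivalent_identifiers` list), from an external member/representative
#' pair table (`provider = "file-external"`), or from nothing
#' (`provider = "none"`: every node is a singleton). Clustering is a
#' union-find over all (node id, equivalent id) pairs, so equivalence chains
#' are followed transitively.
#'
#' The representative of each cluster is chosen deterministically: the
#' lexicographically smallest member that is an actual graph node id,
#' falling back to the lexicographically smallest member overall. An
#' optional `prefix_priority` vector of CURIE prefixes (e.g.
#' `c("CHEBI", "PUBCHEM.COMPOUND")`) ranks members with earlier-listed
#' prefixes first, before the lexicographic tie-break.
#'
#' @param nodes Node `data.table` from a [kg_graph()] (or the graph itself).
#' @param provider `"file"`, `"file-external"` or `"none"`.
#' @param cluster_pairs For `"file-external"`: a two-column object
#'   (member, representative/partner) of CURIE pairs, or a path to such a
#'   TSV file (no header required; a `member<TAB>representative` header row
#'   is tolerated).
#' @param prefix_priority Optional character vector of preferred CURIE
#'   prefixes for representative selection.
#' @return A `kg_eqmap`: list with `representative` (named character vector,
#'   member -> representative) and `clusters` (named list,
#'   representative -> sorted members).
#' @export
build_equivalence_map <- function(nodes, provider = c("file", "file-external", "none"),
                                  cluster_pairs = NULL, prefix_priority = NULL) {
  provider <- match.arg(provider)
  if (inherits(nodes, "kg_graph")) nodes <- nodes$nodes
  node_ids <- nodes$id
  pairs <- switch(provider,
    none = NULL,
    file = {
      eq <- nodes$equivalent_identifiers
      n_each <- lengths(eq)
      if (sum(n_each)) {
        cbind(rep(node_ids, n_each), unlist(eq, use.names = FALSE))
      } else NULL
    },
    `file-external` = {
      if (is.character(cluster_pairs) && length(cluster_pairs) == 1L) {
        cluster_pairs <- read_cluster_pairs(cluster_pairs)
      }
      if (is.null(cluster_pairs)) NULL else as.matrix(cluster_pairs[, 1:2])
    }
  )
  members <- unique(c(node_ids, if (!is.null(pairs)) as.vector(pairs)))
  parent <- seq_along(members)
  idx <- stats::setNames(seq_along(members), members)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]  # path halving
      i <- parent[i]
    }
    i
  }
  if (!is.null(pairs)) {
    a <- idx[pairs[, 1L]]
    b <- idx[pairs[, 2L]]
    for (k in seq_along(a)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[rb] <- ra
    }
  }
  root <- vapply(seq_along(members), find, integer(1))
  clusters <- split(members, root)
  is_node <- members %in% node_ids
  rep_of_cluster <- vapply(clusters, function(m) {
    pick_representative(m, is_node[idx[m]], prefix_priority)
  }, character(1))
  representative <- stats::setNames(
    rep_of_cluster[match(root, as.integer(names(clusters)))], members
  )
  clusters_out <- stats::setNames(lapply(clusters, sort), rep_of_cluster)
  clusters_out <- clusters_out[order(names(clusters_out))]
  structure(
    list(representative = representative, clusters = clusters_out),
    class = "kg_eqmap"
  )
}

pick_representative <- function(members, is_node, prefix_priority) {
  pool <- if (any(is_node)) members[is_node] else members
  if (!is.null(prefix_priority)) {
    prefixes <- sub(":.*$", "", pool)
    rank <- match(prefixes, prefix_priority)
    rank[is.na(rank)] <- length(prefix_priority) + 1L
    pool <- pool[order(rank, pool)]
    pool[1L]
  } else {
    min(pool)
  }
}

#' @export
print.kg_eqmap <- function(x, ...) {
  multi <- sum(lengths(x$clusters) > 1L)
  cat(sprintf("<kg_eqmap> %d members in %d clusters (%d multi-member)\n",
              length(x$representative), length(x$clusters), multi))
  invisible(x)
}

read_cluster_pairs <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = FALSE, colClasses = "character")
  if (!ncol(dt) >= 2L) abort_format("cluster file needs two tab-separated columns", file = path)
  m <- as.matrix(dt[, 1:2])
  # tolerate a header row
  if (nrow(m) && identical(tolower(m[1L, 1L]), "member")) m <- m[-1L, , drop = FALSE]
  m
}

#' Representative of a CURIE under an equivalence map
#'
#' CURIEs unknown to the map are their own representative.
#'
#' @param eqmap A `kg_eqmap` (or `NULL`, treated as the identity map).
#' @param curie Character vector of CURIEs.
#' @return Character vector of representatives.
#' @export
eq_representative <- function(eqmap, curie) {
  if (is.null(eqmap)) return(curie)
  rep <- unname(eqmap$representative[curie])
  ifelse(is.na(rep), curie, rep)
}

#' Merge equivalent concept nodes
#'
#' Produces the canonicalized graph: one node per equivalence cluster that
#' contains at least one graph node. The merged node carries the
#' representative's id and name, the union of members' categories and
#' equivalent identifiers, and merged properties (the representative's
#' value wins scalar conflicts; losing values are recorded under a
#' `merged_values` property). Every edge's subject/object is remapped to
#' cluster representatives; edges made self-referential purely by merging
#' are dropped and counted; duplicate edges — same (subject, predicate,
#' object, primary knowledge source) — collapse into one, list-unioning
#' their properties.
#'
#' Merge statistics are attached as `attr(result, "canonicalization_stats")`:
#' `nodes_merged`, `edges_deduplicated`, `self_loops_dropped`.
#'
#' @param graph A [kg_graph()].
#' @param eqmap A `kg_eqmap` covering the graph's node ids.
#' @return A canonicalized [kg_graph()]. Applying this operation twice (with
#'   an eqmap rebuilt from its own output) equals applying it once.
#' @export
canonicalize_graph <- function(graph, eqmap) {
  nodes <- graph$nodes
  edges <- graph$edges
  if (!nrow(nodes)) {
    out <- kg_graph(nodes, edges, graph$provenance)
    attr(out, "canonicalization_stats") <-
      list(nodes_merged = 0L, edges_deduplicated = 0L, self_loops_dropped = 0L)
    return(out)
  }
  rep_of <- eq_representative(eqmap, nodes$id)
  groups <- split(seq_len(nrow(nodes)), rep_of)

  merged <- lapply(names(groups), function(rep_id) {
    rows <- groups[[rep_id]]
    # deterministic merge order: representative first, then sorted ids
    rows <- rows[order(nodes$id[rows] != rep_id, nodes$id[rows])]
    ids <- nodes$id[rows]
    nm <- nodes$name[rows]
    name <- if (any(!is.na(nm))) nm[!is.na(nm)][1L] else NA_character_
    cats <- sort(unique(unlist(nodes$categories[rows], use.names = FALSE)))
    eqv <- sort(unique(c(ids, rep_id, unlist(nodes$equivalent_identifiers[rows], use.names = FALSE))))
    props <- list()
    conflicts <- list()
    for (r in rows) {
      for (p in names(nodes$properties[[r]])) {
        v <- nodes$properties[[r]][[p]]
        if (is.null(props[[p]])) {
          props[[p]] <- v
        } else if (!identical(props[[p]], v)) {
          conflicts[[p]] <- unique(c(conflicts[[p]], setdiff(v, props[[p]])))
        }
      }
    }
    if (length(conflicts)) props$merged_values <- conflicts
    list(id = rep_id, name = name, categories = cats,
         equivalent_identifiers = eqv, properties = props)
  })
  new_nodes <- data.table::data.table(
    id = vapply(merged, `[[`, character(1), "id"),
    name = vapply(merged, `[[`, character(1), "name"),
    categories = lapply(merged, `[[`, "categories"),
    equivalent_identifiers = lapply(merged, `[[`, "equivalent_identifiers"),
    properties = lapply(merged, `[[`, "properties")
  )
  data.table::setorder(new_nodes, id)

  self_loops_dropped <- 0L
  edges_deduped <- 0L
  if (nrow(edges)) {
    new_subj <- eq_representative(eqmap, edges$subject)
    new_obj <- eq_representative(eqmap, edges$object)
    created_loop <- new_subj == new_obj & edges$subject != edges$object
    self_loops_dropped <- sum(created_loop)
    keep <- which(!created_loop)
    edges <- edges[keep]
    edges[, `:=`(subject = new_subj[keep], object = new_obj[keep])]
    key <- paste(edges$subject, edges$predicate, edges$object,
                 ifelse(is.na(edges$primary_knowledge_source), "",
                        edges$primary_knowledge_source), sep = "\x1f")
    dup_groups <- split(seq_len(nrow(edges)), key)
    edges_deduped <- nrow(edges) - length(dup_groups)
    if (edges_deduped > 0L) {
      rows <- lapply(dup_groups, function(ix) {
        ix <- ix[order(edges$id[ix])]
        if (length(ix) == 1L) return(edges[ix])
        props <- list()
        for (i in ix) {
          for (p in names(edges$properties[[i]])) {
            props[[p]] <- unique(c(props[[p]], edges$properties[[i]][[p]]))
          }
        }
        first <- edges[ix[1L]]
        data.table::set(first, i = 1L, j = "properties", value = list(list(props)))
        first
      })
      edges <- data.table::rbindlist(rows)
    }
    data.table::setorder(edges, id)
  }
  out <- kg_graph(new_nodes, edges, graph$provenance)
  attr(out, "canonicalization_stats") <- list(
    nodes_merged = nrow(nodes) - nrow(new_nodes),
    edges_deduplicated = as.integer(edges_deduped),
    self_loops_dropped = as.integer(self_loops_dropped)
  )
  out
}
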