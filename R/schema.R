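#' Load a category/predicate schema
#'
#' Reads the semantic layer the engine reasons over: two rooted hierarchies
#' (node categories and edge predicates), with per-predicate symmetry,
#' canonical-direction and inverse metadata. The file format is a small YAML
#' or JSON document standing in for a full Biolink Model release:
#'
#' ```yaml
#' categories:
#'   - name: NamedThing
#'   - name: ChemicalEntity
#'     parents: [NamedThing]
#' predicates:
#'   - name: related_to
#'   - name: interacts_with
#'     parents: [related_to]
#'     symmetric: true
#'   - name: treats
#'     parents: [affects]
#'     canonical: true
#'     inverse: treated_by
#' ```
#'
#' Labels may carry a `biolink:` prefix, which is stripped at parse time;
#' matching is case-sensitive afterwards. Both hierarchies must be DAGs with
#' exactly one root (an element with no parents). Multiple parents are
#' allowed (Biolink mixins create multi-parent elements). Reflexive
#' ancestor/descendant closures are precomputed at load so hierarchy lookups
#' at query time are constant-time.
#'
#' Predicate metadata invariants enforced here:
#' * a symmetric predicate has no inverse (it is its own inverse);
#' * if predicate P declares inverse Q, then Q must declare inverse P, and
#'   exactly one of the pair is canonical.
#'
#' @param document Path to a `.yaml`/`.yml`/`.json` schema file, or an
#'   already-parsed list with `categories` and `predicates` entries.
#' @return A `kg_schema` object.
#' @examples
#' sch <- load_schema(system.file("extdata", "mini_schema.yaml", package = "kghop"))
#' descendants(sch, "ChemicalEntity", "category")
#' canonical_form(sch, "treated_by")
#' @export
load_schema <- function(document) {
  if (is.character(document) && length(document) == 1L) {
    ext <- tolower(tools::file_ext(document))
    doc <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(document)
    } else if (ext == "json") {
      jsonlite::fromJSON(document, simplifyDataFrame = FALSE)
    } else {
      abort_schema_invalid(sprintf("unrecognized schema file extension: '%s'", ext))
    }
  } else if (is.list(document)) {
    doc <- document
  } else {
    abort_schema_invalid("schema document must be a file path or a list")
  }
  if (!is.list(doc$categories) || !is.list(doc$predicates)) {
    abort_schema_invalid("schema document must contain 'categories' and 'predicates' lists")
  }

  categories <- parse_schema_elements(doc$categories, "category")
  predicates <- parse_schema_elements(doc$predicates, "predicate")

  validate_hierarchy(categories, "category")
  validate_hierarchy(predicates, "predicate")
  validate_predicate_metadata(predicates)

  schema <- structure(
    list(
      categories = categories,
      predicates = predicates,
      category_root = find_root(categories, "category"),
      predicate_root = find_root(predicates, "predicate")
    ),
    class = "kg_schema"
  )
  schema$closure <- list(
    category = element_closures(categories),
    predicate = element_closures(predicates)
  )
  schema
}

#' @export
print.kg_schema <- function(x, ...) {
  cat(sprintf(
    "<kg_schema> %d categories (root: %s), %d predicates (root: %s)\n",
    length(x$categories), x$category_root, length(x$predicates), x$predicate_root
  ))
  invisible(x)
}

# strips an optional "biolink:" CURIE prefix from labels
strip_label_prefix <- function(x) sub("^biolink:", "", x)

parse_schema_elements <- function(entries, kind) {
  known <- c("name", "parents", "symmetric", "canonical", "inverse")
  out <- list()
  for (e in entries) {
    if (is.null(e$name)) abort_schema_invalid(sprintf("%s entry missing 'name'", kind))
    extra <- setdiff(names(e), known)
    if (length(extra)) {
      warning(sprintf(
        "ignoring unknown field(s) in %s '%s': %s",
        kind, e$name, paste(extra, collapse = ", ")
      ), call. = FALSE)
    }
    name <- strip_label_prefix(e$name)
    if (name %in% names(out)) {
      abort_schema_invalid(sprintf("duplicate %s label: '%s'", kind, name))
    }
    el <- list(
      name = name,
      parents = strip_label_prefix(as.character(e$parents %||% character())),
      kind = kind
    )
    if (kind == "predicate") {
      el$symmetric <- isTRUE(e$symmetric)
      el$canonical <- isTRUE(e$canonical)
      el$inverse <- if (is.null(e$inverse)) NA_character_ else strip_label_prefix(e$inverse)
    }
    out[[name]] <- el
  }
  out
}

validate_hierarchy <- function(elements, kind) {
  labels <- names(elements)
  for (el in elements) {
    missing <- setdiff(el$parents, labels)
    if (length(missing)) {
      abort_schema_invalid(sprintf(
        "%s '%s' lists unknown parent(s): %s", kind, el$name,
        paste(missing, collapse = ", ")
      ))
    }
  }
  # Kahn's algorithm: anything left over sits on a cycle
  indeg <- vapply(elements, function(el) length(el$parents), integer(1))
  children <- split_children(elements)
  queue <- labels[indeg == 0L]
  seen <- 0L
  while (length(queue)) {
    x <- queue[[1L]]; queue <- queue[-1L]; seen <- seen + 1L
    for (ch in children[[x]]) {
      indeg[[ch]] <- indeg[[ch]] - 1L
      if (indeg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(labels)) {
    member <- labels[indeg > 0L][1L]
    abort_schema_invalid(sprintf(
      "%s hierarchy contains a cycle involving '%s'", kind, member
    ))
  }
  roots <- labels[vapply(elements, function(el) length(el$parents) == 0L, logical(1))]
  if (length(roots) != 1L) {
    abort_schema_invalid(sprintf(
      "%s hierarchy must have exactly one root, found: %s",
      kind, paste(roots, collapse = ", ")
    ))
  }
  invisible(TRUE)
}

validate_predicate_metadata <- function(predicates) {
  for (p in predicates) {
    if (p$symmetric && !is.na(p$inverse)) {
      abort_schema_invalid(sprintf(
        "symmetric predicate '%s' must not declare an inverse", p$name
      ))
    }
    if (!is.na(p$inverse)) {
      q <- predicates[[p$inverse]]
      if (is.null(q)) {
        abort_schema_invalid(sprintf(
          "predicate '%s' declares unknown inverse '%s'", p$name, p$inverse
        ))
      }
      if (is.na(q$inverse) || q$inverse != p$name) {
        abort_schema_invalid(sprintf(
          "predicate '%s' has inverse '%s', but '%s' does not declare '%s' as its inverse",
          p$name, p$inverse, p$inverse, p$name
        ))
      }
      if (p$canonical + q$canonical != 1L) {
        abort_schema_invalid(sprintf(
          "exactly one of the inverse pair {%s, %s} must be canonical", p$name, q$name
        ))
      }
    }
  }
  invisible(TRUE)
}

find_root <- function(elements, kind) {
  names(elements)[vapply(elements, function(el) length(el$parents) == 0L, logical(1))]
}

split_children <- function(elements) {
  children <- stats::setNames(vector("list", length(elements)), names(elements))
  for (el in elements) {
    for (p in el$parents) children[[p]] <- c(children[[p]], el$name)
  }
  children
}

# reflexive-transitive closures, memoized bottom-up over the DAG
element_closures <- function(elements) {
  labels <- names(elements)
  anc <- stats::setNames(vector("list", length(labels)), labels)
  compute_anc <- function(label) {
    if (!is.null(anc[[label]])) return(anc[[label]])
    res <- label
    for (p in elements[[label]]$parents) res <- c(res, compute_anc(p))
    res <- unique(res)
    anc[[label]] <<- res
    res
  }
  for (l in labels) compute_anc(l)
  desc <- stats::setNames(replicate(length(labels), character(), simplify = FALSE), labels)
  for (l in labels) {
    for (a in anc[[l]]) desc[[a]] <- c(desc[[a]], l)
  }
  list(ancestors = anc, descendants = lapply(desc, unique))
}

schema_elements <- function(schema, kind) {
  switch(kind,
    category = schema$categories,
    predicate = schema$predicates,
    abort_unknown_element(kind, "kind")
  )
}

#' Hierarchy closure lookups
#'
#' `descendants()` returns the reflexive-transitive descendant set of a
#' schema label; `ancestors()` the reflexive-transitive ancestor set. Both
#' are precomputed at [load_schema()] time, so these are constant-time
#' lookups.
#'
#' @param schema A `kg_schema`.
#' @param label A category or predicate label (optionally `biolink:`-prefixed).
#' @param kind `"category"` or `"predicate"`.
#' @return Character vector of labels, always including `label` itself.
#' @export
descendants <- function(schema, label, kind = c("category", "predicate")) {
  kind <- match.arg(kind)
  label <- strip_label_prefix(label)
  res <- schema$closure[[kind]]$descendants[[label]]
  if (is.null(res)) abort_unknown_element(label, kind)
  res
}

#' @rdname descendants
#' @export
ancestors <- function(schema, label, kind = c("category", "predicate")) {
  kind <- match.arg(kind)
  label <- strip_label_prefix(label)
  res <- schema$closure[[kind]]$ancestors[[label]]
  if (is.null(res)) abort_unknown_element(label, kind)
  res
}

#' Canonical form of a predicate
#'
#' Of an inverse predicate pair (e.g. `treats`/`treated_by`) one direction is
#' designated canonical; edges are stored and matched in canonical
#' orientation. Canonical and symmetric predicates (and plain predicates
#' without an inverse) map to themselves with `flipped = FALSE`; a
#' non-canonical predicate with inverse Q maps to Q with `flipped = TRUE`,
#' meaning subject and object swap.
#'
#' @param schema A `kg_schema`.
#' @param predicate Predicate label.
#' @return A list with elements `predicate` (canonical label) and `flipped`.
#' @export
canonical_form <- function(schema, predicate) {
  predicate <- strip_label_prefix(predicate)
  p <- schema$predicates[[predicate]]
  if (is.null(p)) abort_unknown_element(predicate, "predicate")
  if (p$symmetric || is.na(p$inverse) || p$canonical) {
    list(predicate = p$name, flipped = FALSE)
  } else {
    list(predicate = p$inverse, flipped = TRUE)
  }
}

is_symmetric_predicate <- function(schema, predicate) {
  p <- schema$predicates[[predicate]]
  !is.null(p) && isTRUE(p$symmetric)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
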