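#' Knowledge-graph document container
#'
#' A `kg_graph` holds parsed-but-not-yet-indexed node and edge records.
#' Nodes and edges are `data.table`s with list-columns for multi-valued
#' fields; all property values are kept as character vectors (numeric
#' coercion only happens for properties declared numeric in a
#' `trapi_attribute_map`, avoiding silent type drift between the TSV and
#' JSON Lines dialects).
#'
#' @param nodes `data.table` with columns `id`, `name`, `categories` (list),
#'   `equivalent_identifiers` (list), `properties` (list of named lists).
#' @param edges `data.table` with columns `id`, `subject`, `predicate`,
#'   `object`, `primary_knowledge_source`, `properties` (list).
#' @param provenance Free-form list recording source files and format.
#' @return A `kg_graph` object.
#' @export
kg_graph <- function(nodes, edges, provenance = list()) {
  nodes <- data.table::as.data.table(nodes)
  edges <- data.table::as.data.table(edges)
  if (anyDuplicated(nodes$id)) {
    abort_format(sprintf(
      "duplicate node id(s): %s",
      paste(unique(nodes$id[duplicated(nodes$id)]), collapse = ", ")
    ))
  }
  if (anyDuplicated(edges$id)) {
    abort_format(sprintf(
      "duplicate edge id(s): %s",
      paste(unique(edges$id[duplicated(edges$id)]), collapse = ", ")
    ))
  }
  # a node's equivalence list, when present, always contains its own id
  if (nrow(nodes)) {
    nodes[, equivalent_identifiers := Map(function(eq, id) {
      if (length(eq) && !id %in% eq) c(id, eq) else eq
    }, equivalent_identifiers, id)]
  }
  structure(
    list(nodes = nodes, edges = edges, provenance = provenance),
    class = "kg_graph"
  )
}

#' @export
print.kg_graph <- function(x, ...) {
  cat(sprintf("<kg_graph> %d nodes, %d edges\n", nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

empty_nodes_dt <- function() {
  data.table::data.table(
    id = character(), name = character(),
    categories = list(), equivalent_identifiers = list(), properties = list()
  )
}

empty_edges_dt <- function() {
  data.table::data.table(
    id = character(), subject = character(), predicate = character(),
    object = character(), primary_knowledge_source = character(),
    properties = list()
  )
}

NODE_CORE_COLS <- c("id", "name", "category", "categories", "equivalent_identifiers")
EDGE_CORE_COLS <- c("id", "subject", "predicate", "object", "primary_knowledge_source")

#' Read a knowledge graph from KGX flat files
#'
#' Supports the two KGX dialects: tab-separated values with a header row
#' (list-valued cells joined with `|`, no escaping) and JSON Lines (one
#' object per line). Format is auto-detected from the file extension
#' (`.tsv`/`.txt` vs `.jsonl`/`.jsonlines`/`.json`) unless given explicitly.
#'
#' Core node fields are `id`, `name`, `category` (alias `categories`) and
#' `equivalent_identifiers`; core edge fields are `id` (generated
#' deterministically from edge content when absent), `subject`, `predicate`,
#' `object` and `primary_knowledge_source`. Any other column/key lands in
#' the record's `properties` mapping. Category and predicate labels are
#' stripped of an optional `biolink:` prefix at parse time.
#'
#' @param nodes_path,edges_path Paths (or URLs; staged to a local temp file)
#'   to the nodes and edges files.
#' @param format `"tsv"`, `"jsonlines"` or `"auto"`.
#' @param attribute_map Optional `trapi_attribute_map`-style list; properties
#'   whose descriptor declares `value_type` of `"number"`/`"integer"`/
#'   `"float"`/`"double"` are coerced to numeric.
#' @return A [kg_graph()].
#' @export
read_kgx <- function(nodes_path, edges_path, format = c("auto", "tsv", "jsonlines"),
                     attribute_map = NULL) {
  format <- match.arg(format)
  nodes_path <- stage_location(nodes_path)
  edges_path <- stage_location(edges_path)
  nfmt <- if (format == "auto") detect_kgx_format(nodes_path) else format
  efmt <- if (format == "auto") detect_kgx_format(edges_path) else format
  nodes <- if (nfmt == "tsv") read_kgx_nodes_tsv(nodes_path) else read_kgx_nodes_jsonl(nodes_path)
  edges <- if (efmt == "tsv") read_kgx_edges_tsv(edges_path) else read_kgx_edges_jsonl(edges_path)
  if (!is.null(attribute_map)) {
    edges <- coerce_numeric_properties(edges, attribute_map)
    nodes <- coerce_numeric_properties(nodes, attribute_map)
  }
  kg_graph(nodes, edges, provenance = list(
    nodes_file = nodes_path, edges_file = edges_path,
    nodes_format = nfmt, edges_format = efmt
  ))
}

detect_kgx_format <- function(path) {
  ext <- tolower(tools::file_ext(sub("\\.gz$", "", path)))
  if (ext %in% c("tsv", "txt", "tab")) return("tsv")
  if (ext %in% c("jsonl", "jsonlines", "json", "ndjson")) return("jsonlines")
  abort_format(sprintf("cannot auto-detect KGX format from extension '.%s'", ext), file = path)
}

read_tsv_table <- function(path, required, what) {
  dt <- data.table::fread(
    path, sep = "\t", header = TRUE, colClasses = "character",
    quote = "", na.strings = NULL, fill = TRUE
  )
  missing <- setdiff(required, names(dt))
  if (length(missing)) {
    abort_format(sprintf(
      "%s file missing required column(s): %s", what, paste(missing, collapse = ", ")
    ), file = path)
  }
  dt
}

split_pipes <- function(x) {
  if (is.na(x) || !nzchar(x)) character() else strsplit(x, "|", fixed = TRUE)[[1L]]
}

tsv_row_properties <- function(dt, i, extra_cols) {
  props <- list()
  for (col in extra_cols) {
    v <- split_pipes(dt[[col]][i])
    if (length(v)) props[[col]] <- v
  }
  props
}

read_kgx_nodes_tsv <- function(path) {
  dt <- read_tsv_table(path, "id", "nodes")
  if (!nrow(dt)) return(empty_nodes_dt())
  cat_col <- if ("category" %in% names(dt)) "category" else
    if ("categories" %in% names(dt)) "categories" else NULL
  extra <- setdiff(names(dt), NODE_CORE_COLS)
  n <- nrow(dt)
  data.table::data.table(
    id = dt$id,
    name = if ("name" %in% names(dt)) ifelse(nzchar(dt$name), dt$name, NA_character_)
           else rep(NA_character_, n),
    categories = lapply(seq_len(n), function(i) {
      if (is.null(cat_col)) character()
      else strip_label_prefix(split_pipes(dt[[cat_col]][i]))
    }),
    equivalent_identifiers = lapply(seq_len(n), function(i) {
      if ("equivalent_identifiers" %in% names(dt)) split_pipes(dt$equivalent_identifiers[i])
      else character()
    }),
    properties = lapply(seq_len(n), function(i) tsv_row_properties(dt, i, extra))
  )
}

read_kgx_edges_tsv <- function(path) {
  dt <- read_tsv_table(path, c("subject", "predicate", "object"), "edges")
  if (!nrow(dt)) return(empty_edges_dt())
  extra <- setdiff(names(dt), EDGE_CORE_COLS)
  n <- nrow(dt)
  props <- lapply(seq_len(n), function(i) tsv_row_properties(dt, i, extra))
  pks <- if ("primary_knowledge_source" %in% names(dt)) {
    ifelse(nzchar(dt$primary_knowledge_source), dt$primary_knowledge_source, NA_character_)
  } else rep(NA_character_, n)
  subject <- dt$subject
  predicate <- strip_label_prefix(dt$predicate)
  object <- dt$object
  bad <- which(!nzchar(predicate))
  if (length(bad)) {
    abort_format("empty predicate", file = path, line = bad[1L] + 1L)
  }
  id <- if ("id" %in% names(dt)) dt$id else rep("", n)
  need_id <- which(!nzchar(id))
  for (i in need_id) {
    id[i] <- edge_content_id(subject[i], predicate[i], object[i], pks[i], props[[i]])
  }
  data.table::data.table(
    id = id, subject = subject, predicate = predicate, object = object,
    primary_knowledge_source = pks, properties = props
  )
}

read_jsonl_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  lapply(keep, function(i) {
    tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = TRUE, simplifyDataFrame = FALSE),
      error = function(e) abort_format(
        sprintf("malformed JSON line: %s", conditionMessage(e)), file = path, line = i
      )
    )
  })
}

# property values are normalized to character vectors for cross-dialect parity
prop_chr <- function(v) {
  v <- unlist(v, use.names = FALSE)
  if (is.null(v)) character() else as.character(v)
}

read_kgx_nodes_jsonl <- function(path) {
  recs <- read_jsonl_records(path)
  if (!length(recs)) return(empty_nodes_dt())
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    if (is.null(r$id)) abort_format("node record missing 'id'", file = path, line = i)
    cats <- r$category %||% r$categories %||% character()
    props <- r[setdiff(names(r), NODE_CORE_COLS)]
    props <- props[vapply(props, function(v) length(unlist(v)) > 0L, logical(1))]
    list(
      id = as.character(r$id),
      name = if (is.null(r$name)) NA_character_ else as.character(r$name),
      categories = strip_label_prefix(prop_chr(cats)),
      equivalent_identifiers = prop_chr(r$equivalent_identifiers),
      properties = lapply(props, prop_chr)
    )
  })
  data.table::data.table(
    id = vapply(rows, `[[`, character(1), "id"),
    name = vapply(rows, `[[`, character(1), "name"),
    categories = lapply(rows, `[[`, "categories"),
    equivalent_identifiers = lapply(rows, `[[`, "equivalent_identifiers"),
    properties = lapply(rows, `[[`, "properties")
  )
}

read_kgx_edges_jsonl <- function(path) {
  recs <- read_jsonl_records(path)
  if (!length(recs)) return(empty_edges_dt())
  rows <- lapply(seq_along(recs), function(i) {
    r <- recs[[i]]
    for (f in c("subject", "predicate", "object")) {
      if (is.null(r[[f]]) || !nzchar(r[[f]])) {
        abort_format(sprintf("edge record missing '%s'", f), file = path, line = i)
      }
    }
    props <- r[setdiff(names(r), EDGE_CORE_COLS)]
    props <- props[vapply(props, function(v) length(unlist(v)) > 0L, logical(1))]
    props <- lapply(props, prop_chr)
    pks <- if (is.null(r$primary_knowledge_source)) NA_character_
           else as.character(r$primary_knowledge_source)
    subject <- as.character(r$subject)
    predicate <- strip_label_prefix(as.character(r$predicate))
    object <- as.character(r$object)
    id <- if (is.null(r$id) || !nzchar(r$id)) {
      edge_content_id(subject, predicate, object, pks, props)
    } else as.character(r$id)
    list(id = id, subject = subject, predicate = predicate, object = object,
         primary_knowledge_source = pks, properties = props)
  })
  data.table::data.table(
    id = vapply(rows, `[[`, character(1), "id"),
    subject = vapply(rows, `[[`, character(1), "subject"),
    predicate = vapply(rows, `[[`, character(1), "predicate"),
    object = vapply(rows, `[[`, character(1), "object"),
    primary_knowledge_source = vapply(rows, `[[`, character(1), "primary_knowledge_source"),
    properties = lapply(rows, `[[`, "properties")
  )
}

coerce_numeric_properties <- function(dt, attribute_map) {
  numeric_types <- c("number", "integer", "float", "double")
  numeric_props <- names(attribute_map)[vapply(attribute_map, function(d) {
    isTRUE(tolower(d$value_type %||% "") %in% numeric_types)
  }, logical(1))]
  if (!length(numeric_props) || !nrow(dt)) return(dt)
  dt[, properties := lapply(properties, function(p) {
    for (np in intersect(names(p), numeric_props)) {
      v <- suppressWarnings(as.numeric(p[[np]]))
      if (!anyNA(v)) p[[np]] <- v
    }
    p
  })]
  dt
}

#' Write a knowledge graph as KGX JSON Lines
#'
#' Inverse of [read_kgx()] for the JSON Lines dialect: `read_kgx()` of the
#' written files reconstructs an equal `kg_graph` (up to property key order).
#'
#' @param graph A [kg_graph()].
#' @param nodes_path,edges_path Output file paths.
#' @export
write_kgx_jsonlines <- function(graph, nodes_path, edges_path) {
  node_lines <- if (nrow(graph$nodes)) vapply(seq_len(nrow(graph$nodes)), function(i) {
    r <- graph$nodes[i]
    obj <- list(id = r$id)
    if (!is.na(r$name)) obj$name <- r$name
    if (length(r$categories[[1L]])) obj$category <- r$categories[[1L]]
    if (length(r$equivalent_identifiers[[1L]])) {
      obj$equivalent_identifiers <- r$equivalent_identifiers[[1L]]
    }
    obj <- c(obj, r$properties[[1L]])
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, character(1)) else character()
  edge_lines <- if (nrow(graph$edges)) vapply(seq_len(nrow(graph$edges)), function(i) {
    r <- graph$edges[i]
    obj <- list(id = r$id, subject = r$subject, predicate = r$predicate, object = r$object)
    if (!is.na(r$primary_knowledge_source)) {
      obj$primary_knowledge_source <- r$primary_knowledge_source
    }
    obj <- c(obj, r$properties[[1L]])
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, character(1)) else character()
  write_lines_checked(node_lines, nodes_path)
  write_lines_checked(edge_lines, edges_path)
  invisible(NULL)
}

#' Write a knowledge graph as KGX TSV
#'
#' Tab-separated dialect: one header row; list-valued cells joined with `|`.
#' Property columns are the sorted union of property names across records.
#' Nested property values (e.g. the `merged_values` record produced by node
#' merging) are not representable in TSV and are flattened with a warning;
#' use [write_kgx_jsonlines()] for lossless output.
#'
#' @inheritParams write_kgx_jsonlines
#' @export
write_kgx_tsv <- function(graph, nodes_path, edges_path) {
  join <- function(v) paste(unlist(v, use.names = FALSE), collapse = "|")
  nprops <- sort(unique(unlist(lapply(graph$nodes$properties, names))))
  ncols <- c("id", "name", "category", "equivalent_identifiers", nprops)
  nlines <- c(paste(ncols, collapse = "\t"),
    if (nrow(graph$nodes)) vapply(seq_len(nrow(graph$nodes)), function(i) {
      r <- graph$nodes[i]
      cells <- c(
        r$id, if (is.na(r$name)) "" else r$name,
        join(r$categories[[1L]]), join(r$equivalent_identifiers[[1L]]),
        vapply(nprops, function(p) join(r$properties[[1L]][[p]]), character(1))
      )
      paste(cells, collapse = "\t")
    }, character(1)))
  eprops <- sort(unique(unlist(lapply(graph$edges$properties, names))))
  ecols <- c("id", "subject", "predicate", "object", "primary_knowledge_source", eprops)
  elines <- c(paste(ecols, collapse = "\t"),
    if (nrow(graph$edges)) vapply(seq_len(nrow(graph$edges)), function(i) {
      r <- graph$edges[i]
      cells <- c(
        r$id, r$subject, r$predicate, r$object,
        if (is.na(r$primary_knowledge_source)) "" else r$primary_knowledge_source,
        vapply(eprops, function(p) join(r$properties[[1L]][[p]]), character(1))
      )
      paste(cells, collapse = "\t")
    }, character(1)))
  write_lines_checked(nlines, nodes_path)
  write_lines_checked(elines, edges_path)
  invisible(NULL)
}

write_lines_checked <- function(lines, path) {
  ok <- tryCatch({ writeLines(lines, path); TRUE }, error = function(e) e)
  if (!isTRUE(ok)) {
    kghop_abort(sprintf("cannot write '%s': %s", path, conditionMessage(ok)), "kghop_io_error")
  }
}

# --- deterministic edge ids -------------------------------------------------

# 32-bit FNV-1a over UTF-8 bytes; multiplication by the FNV prime
# (2^24 + 403) is split so intermediates stay exact in doubles.
fnv1a32 <- function(s, offset_basis = 2166136261) {
  h <- offset_basis
  for (b in utf8ToInt(enc2utf8(s))) {
    h <- bitwXor_dbl(h, b)
    lo <- h %% 65536
    h <- (lo * 16777216 + h * 403) %% 4294967296
  }
  h
}

bitwXor_dbl <- function(a, b) {
  # xor on doubles that fit in 32 bits (bitwXor needs ints, a may exceed .Machine$integer.max)
  hi_a <- a %/% 2147483648; lo_a <- a %% 2147483648
  lo <- bitwXor(as.integer(lo_a), as.integer(b %% 2147483648))
  hi <- (hi_a + b %/% 2147483648) %% 2
  hi * 2147483648 + lo
}

# stable content hash of an edge: same content -> same id across rebuilds
edge_content_id <- function(subject, predicate, object, pks, properties) {
  props <- if (length(properties)) properties[order(names(properties))] else list()
  key <- paste(
    subject, predicate, object, if (is.na(pks)) "" else pks,
    paste(vapply(seq_along(props), function(i) {
      paste0(names(props)[i], "=", paste(props[[i]], collapse = "|"))
    }, character(1)), collapse = ";"),
    sep = "\x1f"
  )
  paste0("e", hex32(fnv1a32(key)), hex32(fnv1a32(key, offset_basis = 40389779)))
}

hex32 <- function(h) {
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

# --- build configuration ----------------------------------------------------

#' Parse a build-configuration document
#'
#' One JSON document configures one hosted graph. Required slots:
#' `nodes_file`, `edges_file` (paths or URLs) and `endpoint_name` (the URL
#' sub-path, matching `[a-z0-9_]+`). Optional slots with defaults:
#'
#' * `canonicalize` (`FALSE`): merge equivalent concept nodes at build time.
#' * `subclass_sources` (`["subclass_of"]`): predicate labels whose edges
#'   feed the concept subclass closure; entries that are paths to existing
#'   files are read as external two-column (child, parent) TSV pair lists.
#' * `normalization_provider` (`"file"`): `"file"` uses each node's
#'   `equivalent_identifiers`; `"file-external"` reads `cluster_file` (a
#'   two-column member/representative TSV); `"none"` makes every node its
#'   own cluster.
#' * `trapi_attribute_map` (`{}`): maps property names to TRAPI attribute
#'   descriptors (`attribute_type_id`, optional `value_type`).
#' * `schema_file`: category/predicate schema document (a local extension;
#'   defaults to the demo schema shipped with the package).
#'
#' Unknown slots are kept under `$extra` with a warning. Relative file slots
#' are resolved against the config file's directory.
#'
#' @param document Path to a JSON file, a JSON string, or a list.
#' @return A `kg_config` object.
#' @export
parse_config <- function(document) {
  base_dir <- "."
  if (is.character(document) && length(document) == 1L) {
    if (file.exists(document)) {
      base_dir <- dirname(normalizePath(document))
      document <- paste(readLines(document, warn = FALSE), collapse = "\n")
    }
    doc <- tryCatch(
      jsonlite::fromJSON(document, simplifyVector = TRUE, simplifyDataFrame = FALSE),
      error = function(e) abort_config(sprintf("invalid JSON config: %s", conditionMessage(e)))
    )
  } else if (is.list(document)) {
    doc <- document
  } else {
    abort_config("config must be a file path, JSON string, or list")
  }
  for (slot in c("nodes_file", "edges_file")) {
    if (is.null(doc[[slot]]) || !nzchar(doc[[slot]])) {
      abort_config(sprintf("config missing required slot '%s'", slot))
    }
  }
  if (is.null(doc$endpoint_name)) abort_config("config missing required slot 'endpoint_name'")
  if (!grepl("^[a-z0-9_]+$", doc$endpoint_name)) {
    abort_config(sprintf(
      "endpoint_name '%s' must match [a-z0-9_]+", doc$endpoint_name
    ))
  }
  known <- c(
    "nodes_file", "edges_file", "endpoint_name", "trapi_attribute_map",
    "canonicalize", "subclass_sources", "normalization_provider",
    "cluster_file", "schema_file", "kg_version"
  )
  extra <- setdiff(names(doc), known)
  if (length(extra)) {
    warning(sprintf("ignoring unknown config slot(s): %s", paste(extra, collapse = ", ")),
            call. = FALSE)
  }
  provider <- doc$normalization_provider %||% "file"
  if (!provider %in% c("none", "file", "file-external", "service-stub")) {
    abort_config(sprintf("unknown normalization_provider '%s'", provider))
  }
  structure(list(
    nodes_file = doc$nodes_file,
    edges_file = doc$edges_file,
    endpoint_name = doc$endpoint_name,
    trapi_attribute_map = doc$trapi_attribute_map %||% list(),
    canonicalize = isTRUE(doc$canonicalize),
    subclass_sources = as.character(doc$subclass_sources %||% "subclass_of"),
    normalization_provider = provider,
    cluster_file = doc$cluster_file,
    schema_file = doc$schema_file,
    kg_version = doc$kg_version %||% "unversioned",
    base_dir = base_dir,
    extra = doc[extra]
  ), class = "kg_config")
}

# resolves a config location: URLs are staged to a temp file, relative paths
# are resolved against the config directory
resolve_location <- function(loc, base_dir = ".") {
  if (grepl("^https?://", loc)) return(stage_location(loc))
  if (file.exists(loc)) return(loc)
  candidate <- file.path(base_dir, loc)
  if (file.exists(candidate)) return(candidate)
  loc
}

stage_location <- function(path) {
  if (grepl("^https?://", path)) {
    dest <- file.path(tempdir(), basename(path))
    utils::download.file(path, dest, quiet = TRUE)
    dest
  } else path
}
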