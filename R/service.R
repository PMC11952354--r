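#' Build (or restore) an engine bundle for one hosted graph
#'
#' Runs the full build pipeline for a configured knowledge graph: read the
#' KGX files, resolve concept equivalence, optionally canonicalize the
#' graph, compute the concept subclass closure, build the adjacency index,
#' and derive the meta knowledge graph with its test triples. The result is
#' everything the router needs to serve the graph: immutable after build,
#' so any number of concurrent readers can query it with no coordination.
#'
#' When `snapshot` points at a file written by [save_index()] the index and
#' closure are restored from it instead of being rebuilt from the KGX
#' files; the equivalence map and meta-KG are rederived from the restored
#' node and edge tables, so responses are identical to a fresh build.
#'
#' @param config A `kg_config` (see [parse_config()]) or path to one.
#' @param snapshot Optional path to an index snapshot.
#' @param equivalence_provider Optional function `(nodes) -> kg_eqmap`
#'   overriding the configured provider (the pluggable stand-in for an
#'   external normalization service).
#' @return A `kg_engine` bundle.
#' @export
build_engine <- function(config, snapshot = NULL, equivalence_provider = NULL) {
  if (!inherits(config, "kg_config")) config <- parse_config(config)
  schema_file <- config$schema_file %||%
    system.file("extdata", "demo_schema.yaml", package = "kghop")
  schema <- load_schema(resolve_location(schema_file, config$base_dir))

  make_eqmap <- function(nodes) {
    if (!is.null(equivalence_provider)) return(equivalence_provider(nodes))
    switch(config$normalization_provider,
      none = build_equivalence_map(nodes, provider = "none"),
      file = ,
      `service-stub` = build_equivalence_map(nodes, provider = "file"),
      `file-external` = build_equivalence_map(
        nodes, provider = "file-external",
        cluster_pairs = resolve_location(config$cluster_file, config$base_dir)
      )
    )
  }

  if (!is.null(snapshot)) {
    restored <- load_index(snapshot)
    index <- restored$index
    closure <- restored$closure
    eqmap <- make_eqmap(index$nodes)
  } else {
    graph <- read_kgx(
      resolve_location(config$nodes_file, config$base_dir),
      resolve_location(config$edges_file, config$base_dir),
      attribute_map = config$trapi_attribute_map
    )
    eqmap <- make_eqmap(graph$nodes)
    if (config$canonicalize) {
      graph <- canonicalize_graph(graph, eqmap)
      eqmap <- make_eqmap(graph$nodes)
    }
    sources <- config$subclass_sources
    resolved <- vapply(sources, resolve_location, character(1), base_dir = config$base_dir)
    is_file <- file.exists(resolved)
    external_pairs <- if (any(is_file)) {
      do.call(rbind, lapply(resolved[is_file], read_cluster_pairs))
    } else NULL
    closure <- compute_subclass_closure(
      graph,
      subclass_predicates = if (any(!is_file)) sources[!is_file] else "subclass_of",
      external_pairs = external_pairs
    )
    index <- build_index(graph, schema)
  }
  metakg <- build_meta_kg(index, schema)
  structure(list(
    name = config$endpoint_name,
    config = config,
    schema = schema,
    index = index,
    closure = closure,
    eqmap = eqmap,
    metakg = metakg,
    test_triples = build_test_triples(index, metakg),
    build_info = list(
      endpoint_name = config$endpoint_name,
      kg_version = config$kg_version,
      code_version = as.character(utils::packageVersion("kghop")),
      built_at = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      n_nodes = index$stats$n_nodes,
      n_edges = index$stats$n_edges
    )
  ), class = "kg_engine")
}

#' @export
print.kg_engine <- function(x, ...) {
  cat(sprintf("<kg_engine> '%s': %d nodes, %d edges\n",
              x$name, x$build_info$n_nodes, x$build_info$n_edges))
  invisible(x)
}

#' Answer a query through an engine bundle
#'
#' Thin convenience wrapper binding [answer_query()] to a bundle's index,
#' schema, equivalence map, subclass closure and attribute map.
#'
#' @param engine A `kg_engine`.
#' @param qg Query graph or TRAPI message.
#' @return A `kg_answers`.
#' @export
engine_answer <- function(engine, qg) {
  answer_query(qg, engine$index, engine$schema,
               eqmap = engine$eqmap, closure = engine$closure,
               attribute_map = engine$config$trapi_attribute_map)
}

#' Create a multi-graph service registry
#'
#' Registers one or more fully built engine bundles under their endpoint
#' names ("multiplexing": several independent graphs served by one
#' application at separate URL sub-paths). Engines must be fully built
#' before registration; endpoint names must be unique.
#'
#' @param engines A `kg_engine`, a list of them, or a list of configs/paths
#'   (which are built with [build_engine()], logging per-graph counts).
#' @param log_capacity Ring-buffer size for in-memory request/build logs.
#' @return A `kg_service`.
#' @export
kg_service <- function(engines, log_capacity = 1000L) {
  if (inherits(engines, "kg_engine")) engines <- list(engines)
  engines <- lapply(engines, function(e) {
    if (inherits(e, "kg_engine")) e else build_engine(e)
  })
  nms <- vapply(engines, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    abort_config(sprintf("duplicate endpoint_name(s): %s",
                         paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  svc <- structure(list(
    endpoints = stats::setNames(engines, nms),
    log = new.env(parent = emptyenv())
  ), class = "kg_service")
  svc$log$lines <- character()
  svc$log$capacity <- as.integer(log_capacity)
  for (e in engines) {
    service_log(svc, sprintf("loaded endpoint '%s': %d nodes, %d edges",
                             e$name, e$build_info$n_nodes, e$build_info$n_edges))
  }
  svc
}

#' @export
print.kg_service <- function(x, ...) {
  cat(sprintf("<kg_service> endpoints: %s\n", paste(names(x$endpoints), collapse = ", ")))
  invisible(x)
}

service_log <- function(service, line) {
  env <- service$log
  env$lines <- utils::tail(c(env$lines, paste(format(Sys.time(), "%Y-%m-%d %H:%M:%S"), line)),
                           env$capacity)
  invisible(NULL)
}

json_body <- function(x) {
  as.character(jsonlite::toJSON(x, auto_unbox = TRUE, null = "null", digits = NA))
}

# {} rather than [] for empty mappings
as_json_obj <- function(x) if (length(x)) x else structure(list(), names = character())

http_response <- function(status, payload) {
  list(status = as.integer(status),
       headers = list("Content-Type" = "application/json"),
       body = json_body(payload))
}

#' Route an HTTP-style request
#'
#' The service's request handler, exposed as a pure function so it can be
#' driven by any HTTP front end (see [serve()]) or called directly. Engine
#' state is immutable after build, so identical requests always produce
#' identical response bodies.
#'
#' Endpoints, per hosted graph (`/{endpoint_name}/...`; a single-graph
#' service also answers at the root path):
#' * `POST .../query` — answer a TRAPI-style one-hop query message;
#' * `GET .../meta_knowledge_graph` — the meta-KG;
#' * `GET .../sri_test_triples` — exemplar test triples;
#' * `GET .../code_version` — KG and code version plus build metadata;
#' * `GET .../logs?limit=N` — recent in-memory log lines;
#' * `GET /healthcheck` — 200 once all bundles are loaded.
#'
#' Errors: unknown endpoint gives 404 with the known endpoint list; invalid
#' query JSON or query-graph validation failures give 400 with detail;
#' internal failures give 500 with a correlation id (never a stack trace).
#'
#' @param service A `kg_service`.
#' @param method HTTP method string.
#' @param path Request path, e.g. `"/demo/query"`.
#' @param body Request body: a JSON string or an already-parsed list.
#' @param query Named list of query-string parameters (e.g. `list(limit = 10)`).
#' @return A response list: `status`, `headers`, `body` (JSON string).
#' @export
route <- function(service, method, path, body = NULL, query = list()) {
  started <- Sys.time()
  res <- route_impl(service, toupper(method), path, body, query)
  elapsed_ms <- round(as.numeric(difftime(Sys.time(), started, units = "secs")) * 1000, 1)
  service_log(service, sprintf("%s %s -> %d (%.1f ms)", toupper(method), path,
                               res$status, elapsed_ms))
  res
}

route_impl <- function(service, method, path, body, query) {
  segments <- strsplit(sub("^/+", "", sub("\\?.*$", "", path)), "/")[[1L]]
  segments <- segments[nzchar(segments)]
  known <- names(service$endpoints)
  ops <- c("query", "meta_knowledge_graph", "sri_test_triples", "code_version", "logs")

  if (length(segments) == 1L && segments[1L] == "healthcheck") {
    return(http_response(200L, list(status = "ok", endpoints = as.list(known))))
  }
  if (length(segments) >= 1L && segments[1L] %in% known) {
    ep <- segments[1L]
    op <- if (length(segments) >= 2L) segments[2L] else ""
  } else if (length(segments) >= 1L && segments[1L] %in% ops && length(known) == 1L) {
    # single-KG deployments also answer at the root path
    ep <- known[1L]
    op <- segments[1L]
  } else {
    return(http_response(404L, list(
      error = sprintf("unknown endpoint: '%s'", paste(segments, collapse = "/")),
      known_endpoints = as.list(known)
    )))
  }
  engine <- service$endpoints[[ep]]
  if (!op %in% ops) {
    return(http_response(404L, list(
      error = sprintf("unknown operation '%s' for endpoint '%s'", op, ep),
      known_operations = as.list(ops)
    )))
  }
  switch(op,
    query = handle_query(service, engine, method, body),
    meta_knowledge_graph = http_response(200L, list(
      nodes = as_json_obj(lapply(engine$metakg$meta_nodes, function(mn) {
        list(id_prefixes = as.list(mn$id_prefixes))
      })),
      edges = meta_edges_payload(engine$metakg)
    )),
    sri_test_triples = http_response(200L, test_triples_payload(engine)),
    code_version = http_response(200L, engine$build_info),
    logs = {
      limit <- suppressWarnings(as.integer(query$limit %||% 100L))
      if (is.na(limit) || limit < 1L) limit <- 100L
      http_response(200L, list(lines = as.list(utils::tail(service$log$lines, limit))))
    }
  )
}

handle_query <- function(service, engine, method, body) {
  if (method != "POST") {
    return(http_response(405L, list(error = "query endpoint requires POST")))
  }
  if (!is.character(body) && !is.list(body)) {
    return(http_response(400L, list(error = "request body must be a JSON object")))
  }
  parsed <- if (is.character(body)) {
    tryCatch(jsonlite::fromJSON(body, simplifyVector = FALSE), error = function(e) e)
  } else body
  if (inherits(parsed, "error")) {
    return(http_response(400L, list(error = sprintf(
      "invalid JSON body: %s", conditionMessage(parsed)
    ))))
  }
  result <- tryCatch({
    qg <- validate_query(parsed, engine$schema)
    answers <- engine_answer(engine, qg)
    as_trapi_message_payload(answers, qg)
  },
  kghop_query_error = function(e) e,
  kghop_unknown_element = function(e) e,
  kghop_constraint_error = function(e) e,
  error = function(e) e)
  if (inherits(result, "kghop_error")) {
    return(http_response(400L, list(error = conditionMessage(result))))
  }
  if (inherits(result, "error")) {
    cid <- sprintf("%08x", as.integer(stats::runif(1, 0, 2^31 - 1)))
    service_log(service, sprintf("ERROR [%s]: %s", cid, conditionMessage(result)))
    return(http_response(500L, list(error = "internal server error", correlation_id = cid)))
  }
  http_response(200L, result)
}

as_trapi_message_payload <- function(answers, qg) {
  msg <- as_trapi_message(answers, qg)
  msg$message$knowledge_graph$nodes <- as_json_obj(msg$message$knowledge_graph$nodes)
  msg$message$knowledge_graph$edges <- as_json_obj(msg$message$knowledge_graph$edges)
  msg
}

meta_edges_payload <- function(metakg) {
  me <- metakg$meta_edges
  lapply(seq_len(nrow(me)), function(i) list(
    subject = me$subject_category[i],
    predicate = me$predicate[i],
    object = me$object_category[i],
    count = me$count[i]
  ))
}

test_triples_payload <- function(engine) {
  tt <- engine$test_triples
  list(triples = lapply(seq_len(nrow(tt)), function(i) list(
    subject_category = tt$subject_category[i],
    predicate = tt$predicate[i],
    object_category = tt$object_category[i],
    subject_id = tt$subject_id[i],
    object_id = tt$object_id[i]
  )))
}

#' Serve a registry over HTTP
#'
#' Starts a blocking HTTP server (via the `httpuv` package) that dispatches
#' every request through [route()]. Because all query-time state is
#' immutable, the service is also safe to run under any multi-process
#' manager; this built-in server is single-process and intended for local
#' use and development.
#'
#' @param service A `kg_service`, or configs accepted by [kg_service()].
#' @param host,port Bind address.
#' @export
serve <- function(service, host = "127.0.0.1", port = 8080L) {
  if (!inherits(service, "kg_service")) service <- kg_service(service)
  if (!requireNamespace("httpuv", quietly = TRUE)) {
    kghop_abort("serving over HTTP requires the 'httpuv' package", "kghop_config_error")
  }
  message(sprintf("serving %d endpoint(s) at http://%s:%d",
                  length(service$endpoints), host, port))
  httpuv::runServer(host, port, list(
    call = function(req) {
      body <- tryCatch(rawToChar(req$rook.input$read()), error = function(e) NULL)
      params <- parse_query_string(req$QUERY_STRING %||% "")
      route(service, req$REQUEST_METHOD, req$PATH_INFO, body = body, query = params)
    }
  ))
}

parse_query_string <- function(qs) {
  qs <- sub("^\\?", "", qs)
  if (!nzchar(qs)) return(list())
  parts <- strsplit(strsplit(qs, "&", fixed = TRUE)[[1L]], "=", fixed = TRUE)
  vals <- lapply(parts, function(p) if (length(p) > 1L) utils::URLdecode(p[2L]) else "")
  stats::setNames(vals, vapply(parts, `[[`, character(1), 1L))
}
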