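demo_engine <- function() {
  build_engine(system.file("extdata", "demo_kg", "config.json", package = "kghop"))
}

# a second graph with a fully disjoint vocabulary, for multiplex isolation
make_isolated_engine <- function(dir, name) {
  nodes <- file.path(dir, "n.tsv"); edges <- file.path(dir, "e.tsv")
  writeLines(c("id\tname\tcategory",
               sprintf("ZZZ%s:1\talpha-%s\tGene", name, name),
               sprintf("ZZZ%s:2\tbeta-%s\tGene", name, name)), nodes)
  writeLines(c("id\tsubject\tpredicate\tobject",
               sprintf("iso_%s\tZZZ%s:1\tinteracts_with\tZZZ%s:2", name, name, name)),
             edges)
  build_engine(parse_config(list(nodes_file = nodes, edges_file = edges,
                                 endpoint_name = name)))
}

demo_query <- function() {
  list(message = list(query_graph = one_hop(
    s_ids = "CHEBI:46195", o_cats = "Protein", predicates = "interacts_with"
  )))
}

test_that("query responses pass through the engine unchanged", {
  eng <- demo_engine()
  svc <- kg_service(eng)
  res <- route(svc, "POST", "/demo/query", body = jsonlite::toJSON(demo_query(), auto_unbox = TRUE))
  expect_identical(res$status, 200L)
  body <- jsonlite::fromJSON(res$body, simplifyVector = FALSE)
  qg <- validate_query(demo_query(), eng$schema)
  want <- kghop:::as_trapi_message_payload(engine_answer(eng, qg), qg)
  want <- jsonlite::fromJSON(jsonlite::toJSON(want, auto_unbox = TRUE, null = "null"),
                             simplifyVector = FALSE)
  expect_identical(body, want)
  expect_setequal(names(body$message$knowledge_graph$edges), c("T001", "T002"))
  # single-KG deployments answer at the root path too
  res_root <- route(svc, "POST", "/query", body = demo_query())
  expect_identical(res_root$body, res$body)
})

test_that("unknown endpoints and operations yield 404 with known endpoints", {
  svc <- kg_service(demo_engine())
  res <- route(svc, "GET", "/nope/query")
  expect_identical(res$status, 404L)
  expect_true(grepl("demo", res$body))
  expect_identical(route(svc, "GET", "/demo/frobnicate")$status, 404L)
})

test_that("malformed query documents yield 400 with detail, never a crash", {
  svc <- kg_service(demo_engine())
  expect_identical(route(svc, "POST", "/demo/query", body = "{not json")$status, 400L)
  # structurally invalid query graph
  bad <- list(message = list(query_graph = list(
    nodes = list(n0 = list(ids = "CHEBI:46195")), edges = list()
  )))
  res <- route(svc, "POST", "/demo/query", body = bad)
  expect_identical(res$status, 400L)
  expect_true(grepl("query", res$body))
  # unpinned query
  res2 <- route(svc, "POST", "/demo/query",
                body = list(message = list(query_graph = one_hop(s_cats = "Drug"))))
  expect_identical(res2$status, 400L)
  # GET on query is rejected
  expect_identical(route(svc, "GET", "/demo/query")$status, 405L)
})

test_that("multiplexed endpoints are isolated", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  svc <- kg_service(list(make_isolated_engine(d1, "kga"),
                         make_isolated_engine(d2, "kgb")))
  ma <- route(svc, "GET", "/kga/meta_knowledge_graph")$body
  mb <- route(svc, "GET", "/kgb/meta_knowledge_graph")$body
  expect_true(grepl("ZZZkga", ma) && !grepl("ZZZkgb", ma))
  expect_true(grepl("ZZZkgb", mb) && !grepl("ZZZkga", mb))
  qa <- route(svc, "POST", "/kga/query",
              body = list(message = list(query_graph = one_hop(s_ids = "ZZZkga:1"))))
  expect_true(grepl("iso_kga", qa$body) && !grepl("kgb", qa$body))
  # a kga identifier finds nothing in kgb
  qb <- route(svc, "POST", "/kgb/query",
              body = list(message = list(query_graph = one_hop(s_ids = "ZZZkga:1"))))
  body <- jsonlite::fromJSON(qb$body, simplifyVector = FALSE)
  expect_length(body$message$results, 0L)
  # root-path alias is only available for single-KG services
  expect_identical(route(svc, "POST", "/query", body = demo_query())$status, 404L)
})

test_that("identical requests produce byte-identical bodies", {
  svc <- kg_service(demo_engine())
  req <- function() route(svc, "POST", "/demo/query",
                          body = jsonlite::toJSON(demo_query(), auto_unbox = TRUE))
  bodies <- vapply(1:5, function(i) req()$body, character(1))
  expect_identical(unique(bodies), bodies[1L])
})

test_that("auxiliary endpoints expose health, versions, triples, and logs", {
  eng <- demo_engine()
  svc <- kg_service(eng)
  hc <- route(svc, "GET", "/healthcheck")
  expect_identical(hc$status, 200L)
  expect_true(grepl("\"ok\"", hc$body))
  cv <- jsonlite::fromJSON(route(svc, "GET", "/demo/code_version")$body)
  expect_identical(cv$kg_version, "demo-1.0")
  expect_identical(cv$code_version, as.character(utils::packageVersion("kghop")))
  expect_identical(cv$n_edges, 8L)
  tt <- jsonlite::fromJSON(route(svc, "GET", "/demo/sri_test_triples")$body,
                           simplifyVector = FALSE)
  expect_gte(length(tt$triples), 1L)
  lg <- jsonlite::fromJSON(route(svc, "GET", "/demo/logs", query = list(limit = 2))$body,
                           simplifyVector = FALSE)
  expect_lte(length(lg$lines), 2L)
  # requests are logged
  expect_true(any(grepl("GET /demo/code_version", svc$log$lines)))
})

test_that("serving from a snapshot reproduces built responses exactly", {
  eng <- demo_engine()
  snap <- withr::local_tempfile(fileext = ".snapshot")
  save_index(eng$index, eng$closure, snap)
  eng2 <- build_engine(system.file("extdata", "demo_kg", "config.json", package = "kghop"),
                       snapshot = snap)
  svc1 <- kg_service(eng)
  svc2 <- kg_service(eng2)
  battery <- list(
    demo_query(),
    list(message = list(query_graph = one_hop(o_ids = "MONDO:0002048",
                                              predicates = "treats"))),
    list(message = list(query_graph = one_hop(s_ids = "DRUGBANK:DB00316")))
  )
  for (q in battery) {
    expect_identical(
      route(svc1, "POST", "/demo/query", body = q)$body,
      route(svc2, "POST", "/demo/query", body = q)$body
    )
  }
  expect_identical(
    route(svc1, "GET", "/demo/meta_knowledge_graph")$body,
    route(svc2, "GET", "/demo/meta_knowledge_graph")$body
  )
  expect_identical(
    route(svc1, "GET", "/demo/sri_test_triples")$body,
    route(svc2, "GET", "/demo/sri_test_triples")$body
  )
})

test_that("duplicate endpoint names are rejected at registration", {
  eng <- demo_engine()
  expect_error(kg_service(list(eng, eng)), class = "kghop_config_error")
})

test_that("corrupt KGX input aborts the build naming the file", {
  d <- withr::local_tempdir()
  nodes <- file.path(d, "n.tsv")
  writeLines(c("id\tname", "A\tx"), nodes)
  edges <- file.path(d, "e.tsv")
  writeLines(c("id\tsubject\tobject", "x\tA\tA"), edges)  # no predicate column
  cfg <- parse_config(list(nodes_file = nodes, edges_file = edges, endpoint_name = "bad"))
  err <- tryCatch(build_engine(cfg), error = function(e) e)
  expect_s3_class(err, "kghop_format_error")
  expect_true(grepl("e.tsv", conditionMessage(err), fixed = TRUE))
})
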