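test_that("an empty graph and a well-formed fixture validate cleanly", {
  expect_identical(nrow(validate_graph(kg_new())), 0L)
  expect_identical(nrow(validate_graph(tiny_kg())), 0L)
})

test_that("validation flags exactly the planted faults", {
  # event group linked to two studies -> one cardinality violation
  kg <- tiny_kg()
  kg <- kg_add_edges(kg, "Study-EventGroup", "study:NCT2",
                     "eventgroup:NCT1:EG1")
  v <- validate_graph(kg)
  expect_identical(nrow(v), 1L)
  expect_identical(v$rule, "cardinality")
  expect_identical(v$id, "eventgroup:NCT1:EG1")

  # dangling tail -> one referential-integrity violation
  kg <- tiny_kg()
  kg <- kg_add_edges(kg, "Study-Condition", "study:NCT1", "condition:ghost")
  v <- validate_graph(kg)
  expect_identical(nrow(v), 1L)
  expect_identical(v$rule, "dangling_endpoint")
  expect_identical(v$id, "condition:ghost")

  # wrong endpoint type
  kg <- tiny_kg()
  kg <- kg_add_edges(kg, "Study-Condition", "study:NCT1", "organ:gastro")
  expect_identical(validate_graph(kg)$rule, "endpoint_type")

  # missing owning study on a study-specific type
  kg <- tiny_kg()
  kg$nodes$EventGroup$nct_id <- NA_character_
  expect_identical(validate_graph(kg)$rule, "missing_owner")

  # adverse event without its organ edge
  kg <- tiny_kg()
  kg$edges[["AdverseEvent-Organ"]] <-
    kg$edges[["AdverseEvent-Organ"]][0, ]
  v <- validate_graph(kg)
  expect_identical(v$rule, "cardinality")
  expect_identical(v$id, "adverseevent:nausea")
})

test_that("graph statistics count nodes, unique endpoints and edges", {
  st <- graph_statistics(kg_new())
  expect_true(all(st$nodes$n_nodes == 0L))
  expect_true(all(st$relations$n_edges == 0L))

  st <- graph_statistics(tiny_kg())
  sc <- st$relations[st$relations$relation == "Study-Condition", ]
  expect_identical(sc$n_head, 2L)
  expect_identical(sc$n_tail, 3L)
  expect_identical(sc$n_edges, 4L)
  expect_identical(st$nodes$n_nodes[st$nodes$node_type == "Study"], 2L)
})

test_that("per-study group relations are one-to-one on assembled graphs", {
  fx <- generate_fixture(fixture_config(n_studies = 15L, seed = 21L))
  kg <- assemble(fx$tables, fx$dict, fx$lexicon,
                 assemble_config(clusters = 3L, seed = 1L))
  st <- graph_statistics(kg)
  for (rel in c("Study-EventGroup", "Study-BaselineGroup", "Study-DropGroup",
                "Study-OutcomeGroup", "Study-Outcome")) {
    row <- st$relations[st$relations$relation == rel, ]
    tail_n <- st$nodes$n_nodes[st$nodes$node_type == row$tail_type]
    expect_identical(row$n_edges, tail_n)
    expect_identical(row$n_tail, tail_n)
  }
})

test_that("export/import round-trips a graph exactly", {
  kg <- tiny_kg()
  d <- withr::local_tempdir()
  export_graph(kg, d)
  expect_identical(length(list.files(d, pattern = "^nodes_")), 18L)
  expect_identical(length(list.files(d, pattern = "^edges_")), 21L)
  kg2 <- import_graph(d)
  expect_identical(lapply(kg$nodes, as.data.frame),
                   lapply(kg2$nodes, as.data.frame))
  expect_identical(lapply(kg$edges, as.data.frame),
                   lapply(kg2$edges, as.data.frame))

  # attribute values containing the delimiter, quotes and newlines survive
  kg <- kg_add_nodes(kg_new(), "Study", data.frame(
    node_id = "study:X", nct_id = "X",
    title = "tab\there \"quoted\", comma"))
  d2 <- withr::local_tempdir()
  export_graph(kg, d2)
  kg2 <- import_graph(d2)
  expect_identical(kg2$nodes$Study$title, "tab\there \"quoted\", comma")
})

test_that("round-trip is the identity on generated graphs", {
  fx <- generate_fixture(fixture_config(n_studies = 10L, seed = 5L))
  kg <- assemble(fx$tables, fx$dict, fx$lexicon,
                 assemble_config(clusters = 2L, seed = 3L))
  d <- withr::local_tempdir()
  export_graph(kg, d)
  kg2 <- import_graph(d)
  expect_identical(lapply(kg$nodes, as.data.frame),
                   lapply(kg2$nodes, as.data.frame))
  expect_identical(lapply(kg$edges, as.data.frame),
                   lapply(kg2$edges, as.data.frame))
})

test_that("the schema round-trips through its JSON config", {
  sch <- trial_schema()
  f <- withr::local_tempfile(fileext = ".json")
  write_schema(sch, f)
  sch2 <- read_schema(f)
  expect_identical(as.data.frame(sch$node_types),
                   as.data.frame(sch2$node_types))
  expect_identical(as.data.frame(sch$relations),
                   as.data.frame(sch2$relations))
  # malformed configs are rejected
  bad <- sch
  bad$relations$head_type[1] <- "NotAType"
  expect_error(new_trial_schema(bad$node_types, bad$relations),
               "not declared")
})
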