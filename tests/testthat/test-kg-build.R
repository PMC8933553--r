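test_that("the filter cascade excludes studies in fixed stage order", {
  fo <- filter_studies(filter_fixture_tables())
  expect_identical(unname(fo$excluded), c(4L, 2L, 1L))
  expect_identical(length(fo$kept), 3L)
  expect_identical(length(fo$kept) + sum(fo$excluded), fo$n_input)

  # all-complete input keeps everything
  tabs <- filter_fixture_tables()
  tabs$interventions$type <- "Drug"
  tabs$outcome_analyses <- data.frame(nct_id = tabs$studies$nct_id,
                                      id = as.character(1:10),
                                      outcome_id = "1", method = "t",
                                      p_value = "1")
  tabs$conditions <- data.frame(nct_id = tabs$studies$nct_id, name = "c")
  fo <- filter_studies(tabs)
  expect_identical(unname(fo$excluded), c(0L, 0L, 0L))
  expect_identical(length(fo$kept), 10L)
})

test_that("the kept set is invariant to input row order", {
  tabs <- filter_fixture_tables()
  fo1 <- filter_studies(tabs)
  tabs2 <- tabs
  set.seed(2)
  for (nm in names(tabs2)) {
    t <- data.table::as.data.table(tabs2[[nm]])
    if (nrow(t) > 1) tabs2[[nm]] <- t[sample(nrow(t))]
  }
  fo2 <- filter_studies(tabs2)
  expect_identical(fo1$kept, fo2$kept)
  expect_identical(fo1$excluded, fo2$excluded)
})

test_that("a minimal single-study fixture assembles to the hand count", {
  kg <- assemble(minimal_tables(), tiny_dict(), tiny_lexicon(),
                 assemble_config(clusters = 1L, seed = 1L))
  st <- graph_statistics(kg)
  counts <- stats::setNames(st$nodes$n_nodes, st$nodes$node_type)
  expect_identical(counts[["Study"]], 1L)
  expect_identical(counts[["Condition"]], 1L)
  expect_identical(counts[["DrugTerm"]], 1L)
  expect_identical(counts[["EventGroup"]], 1L)
  expect_identical(counts[["AdverseEvent"]], 1L)
  expect_identical(counts[["Organ"]], 1L)
  expect_identical(counts[["OutcomeGroup"]], 1L)
  expect_identical(counts[["Outcome"]], 1L)
  expect_identical(counts[["OutcomeMeasurement"]], 1L)
  expect_identical(counts[["OutcomeAnalysis"]], 1L)
  expect_identical(counts[["Method"]], 1L)
  expect_identical(counts[["ClusterOutcome"]], 1L)
  rel <- stats::setNames(st$relations$n_edges, st$relations$relation)
  expect_identical(rel[["Study-Condition"]], 1L)
  expect_identical(rel[["Study-EventGroup"]], 1L)
  expect_identical(rel[["Study-StudiedDrug"]], 1L)
  expect_identical(rel[["Study-UsedDrug"]], 0L)
  expect_identical(rel[["EventGroup-AdverseEvent"]], 1L)
  expect_identical(rel[["AdverseEvent-Organ"]], 1L)
  expect_identical(rel[["Outcome-OutcomeMeasurement"]], 1L)
  expect_identical(rel[["OutcomeGroup-OutcomeAnalysis"]], 1L)
  expect_identical(rel[["OutcomeAnalysis-Method"]], 1L)
  expect_identical(nrow(validate_graph(kg)), 0L)
  # the event-group title mentions the studied drug
  expect_identical(kg$edges[["Drug-EventGroup"]]$head_id,
                   "drugterm:naltrexone")
})

test_that("an empty kept set yields an empty graph", {
  tabs <- minimal_tables()
  tabs$interventions$type <- "Device"
  kg <- assemble(tabs, tiny_dict(), tiny_lexicon())
  expect_identical(sum(graph_statistics(kg)$nodes$n_nodes), 0L)
})

test_that("rows referencing missing parents are skipped with a warning", {
  tabs <- minimal_tables()
  tabs$reported_events <- rbind(
    tabs$reported_events,
    data.frame(nct_id = "NCT1", group_id = "GHOST", ae_term = "Nausea",
               organ_system = "x", subjects_affected = "1",
               subjects_at_risk = "2"))
  expect_warning(kg <- assemble(tabs, tiny_dict(), tiny_lexicon(),
                                assemble_config(clusters = 1L)),
                 "missing event group")
  expect_identical(nrow(validate_graph(kg)), 0L)
  expect_identical(nrow(kg$edges[["EventGroup-AdverseEvent"]]), 1L)
})

test_that("a generated 50-study snapshot assembles to a valid graph", {
  fx <- generate_fixture(fixture_config(n_studies = 50L, n_no_drug = 6L,
                                        n_no_analysis = 3L,
                                        n_no_condition = 2L, seed = 33L))
  kg <- assemble(fx$tables, fx$dict, fx$lexicon,
                 assemble_config(clusters = 5L, seed = 1L))
  expect_identical(nrow(validate_graph(kg)), 0L)
  st <- graph_statistics(kg)
  expect_identical(
    st$nodes$n_nodes[st$nodes$node_type == "Study"],
    length(fx$truth$study_flags[fx$truth$study_flags == "complete"]))
  # structural one-to-one: event-group edges equal event-group nodes
  eg <- st$relations[st$relations$relation == "Study-EventGroup", ]
  expect_identical(eg$n_edges,
                   st$nodes$n_nodes[st$nodes$node_type == "EventGroup"])
})
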