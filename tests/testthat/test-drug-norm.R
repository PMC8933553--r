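test_that("tree-code classification keeps drugs and excludes classes", {
  expect_true(is_drug_code("D02.241.223.701.430"))
  expect_false(is_drug_code("D26.310"))
  expect_false(is_drug_code("C01.252"))
  expect_false(is_drug_code("D23.101.140"))
  expect_false(is_drug_code("D26"))
  expect_false(is_drug_code("D26.255.100"))
  expect_true(is_drug_code("D23.100"))
  # prefix descent is dotted, not textual
  expect_true(is_drug_code("D26310"))
  expect_false(is_drug_code(""))
})

test_that("code filtering drops non-specific lexicon entries", {
  raw <- data.frame(surface = c("ibuprofen", "placebo mix", "nocode"),
                    tree_code = c("D02.241.223.701.430", "D26.310", NA),
                    canonical = c("Ibuprofen", "placebo mix", "nocode"),
                    generic = NA)
  kept <- filter_lexicon_codes(raw)
  expect_identical(kept$surface, c("ibuprofen", "nocode"))
})

test_that("mention tagging is case-insensitive, bounded and longest-first", {
  lex <- tiny_lexicon()
  m <- tag_mentions("Naltrexone 50 Mg Oral Tablet", lex)
  expect_identical(m$surface, "Naltrexone")

  m <- tag_mentions("tramadol/diclofenac 25/25", lex)
  expect_identical(m$surface, c("tramadol", "diclofenac"))

  empty_lex <- drug_lexicon(data.frame(surface = "x", tree_code = NA,
                                       canonical = "x", generic = NA))
  expect_identical(nrow(tag_mentions("placebo saline", empty_lex)), 0L)

  # longest match wins and spans never overlap
  m <- tag_mentions("losartan potassium tablets", lex)
  expect_identical(m$surface, "losartan potassium")
  expect_true(all(diff(m$start) > 0))

  # substrings inside words are not matches
  expect_identical(nrow(tag_mentions("xlosartanx", lex)), 0L)
})

test_that("surrounding filler never changes the tagged set", {
  lex <- tiny_lexicon()
  set.seed(8)
  fillers <- c("oral", "mg", "daily", "solution", "extended", "release")
  for (i in 1:20) {
    core <- sample(c("cozaar", "ibuprofen", "tramadol"), 1)
    pre <- paste(sample(fillers, 2), collapse = " ")
    post <- paste(sample(fillers, 2), collapse = " ")
    m <- tag_mentions(paste(pre, core, post), lex)
    expect_identical(tolower(m$surface), core)
  }
})

test_that("mention canonicalization follows the resolution order", {
  lex <- tiny_lexicon()
  expect_identical(normalize_mention("cozaar", lex), "losartan")
  expect_identical(normalize_mention("Losartan Potassium", lex), "losartan")
  expect_identical(normalize_mention("tvr", lex), "Telaprevir")
  # abbreviation whose full name is outside the lexicon falls back to it
  expect_identical(normalize_mention("umec", lex), "Umeclidinium")
  # investigational identifier keeps itself
  expect_identical(normalize_mention("pf-06669571", lex), "pf-06669571")
  # override wins over everything
  expect_identical(
    normalize_mention("cozaar", lex, overrides = c(cozaar = "custom")),
    "custom")
  # idempotent on its own outputs
  for (s in c("cozaar", "tvr", "pf-06669571")) {
    once <- normalize_mention(s, lex)
    expect_identical(normalize_mention(once, lex), once)
  }
})

test_that("drug edges split into studied and used, disjoint per study", {
  mentions <- data.table::data.table(
    nct_id = c("S1", "S1", "S1", "S2"),
    source = c("intervention", "group_description", "group_description",
               "group_title"),
    group_id = c(NA, "EG1", "EG1", "EG2"),
    group_type = c(NA, "Reported Event", "Reported Event", "Reported Event"),
    surface = c("Naltrexone", "ibuprofen", "naltrexone", "cozaar"),
    canonical = c("Naltrexone", "Ibuprofen", "Naltrexone", "losartan"))
  out <- assign_drug_edges(mentions)
  expect_setequal(out$drug_nodes$term,
                  c("Ibuprofen", "losartan", "Naltrexone"))
  # intervention-sourced and title-sourced terms are studied
  expect_true(all(c("drugterm:naltrexone", "drugterm:losartan") %in%
                    out$studied_edges$tail_id))
  # description-only term is used
  expect_identical(out$used_edges$tail_id, "drugterm:ibuprofen")
  # studied wins: naltrexone also appears in a description but not in used
  both <- merge(out$studied_edges, out$used_edges,
                by = c("head_id", "tail_id"))
  expect_identical(nrow(both), 0L)
  # event-group mentions yield drug/event-group edges
  expect_identical(sort(out$drug_eventgroup_edges$tail_id),
                   c("eventgroup:S1:EG1", "eventgroup:S1:EG1",
                     "eventgroup:S2:EG2"))
  # empty input
  empty <- assign_drug_edges(mentions[0, ])
  expect_identical(nrow(empty$drug_nodes), 0L)
})

test_that("brand, generic and abbreviated variants collapse to one node", {
  fx <- generate_fixture(fixture_config(n_studies = 10L, seed = 13L))
  tr <- fx$truth$drug
  got <- normalize_mention(tr$surface, fx$lexicon)
  expect_identical(got, tr$canonical)
  out <- assign_drug_edges(collect_drug_mentions(
    fx$tables$interventions, fx$tables$result_groups, fx$lexicon))
  expect_lte(nrow(out$drug_nodes), nrow(fixture_drug_catalog(10L)))
  expect_true(all(tolower(out$drug_nodes$term) %in%
                    tolower(fixture_drug_catalog(10L)$canonical)))
})
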