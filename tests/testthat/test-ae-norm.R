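test_that("the cascade stops at the first matching stage", {
  dict <- tiny_dict()

  r <- normalize_ae("Nausea", dict)
  expect_identical(r$normalized_term, "Nausea")
  expect_true(r$matched)
  expect_identical(r$stage, 0L)

  r <- normalize_ae("Altered pitch perception (pitch seemed lower)", dict)
  expect_identical(r$normalized_term, "Altered pitch perception")
  expect_identical(r$stage, 1L)

  r <- normalize_ae("Throat tightness - Baseline Phase", dict)
  expect_identical(r$normalized_term, "Throat tightness")
  expect_identical(r$stage, 2L)

  r <- normalize_ae("the knee pains", dict)
  expect_identical(r$normalized_term, "knee pain")
  expect_identical(r$stage, 3L)

  r <- normalize_ae("Cholecyctitis", dict)
  expect_identical(r$normalized_term, "Cholecystitis")
  expect_identical(r$stage, 4L)

  r <- normalize_ae("completely unrelated gibberish", dict)
  expect_false(r$matched)
  expect_identical(r$normalized_term,
                   simplify_tokens("completely unrelated gibberish"))

  expect_error(normalize_ae("", dict), "empty")
  expect_error(normalize_ae("  ", dict), "empty")
})

test_that("stage-4 rescue breaks ties by distance then lexicographic order", {
  dict <- term_hierarchy(data.frame(term = c("abcd", "abce"),
                                    level = c(2L, 2L), parent = NA))
  r <- normalize_ae("abcf", dict)
  expect_identical(r$stage, 4L)
  expect_identical(r$normalized_term, "abcd")
})

test_that("curation overrides take precedence over the cascade", {
  dict <- tiny_dict()
  r <- normalize_ae("weird local phrasing", dict,
                    overrides = c("weird local phrasing" = "Nausea"))
  expect_true(r$matched)
  expect_identical(r$normalized_term, "Nausea")
})

test_that("level-1 terms roll up to their level-2 parent", {
  dict <- tiny_dict()
  expect_identical(rollup_level1("Eye itching", dict), "itchy eyes")
  expect_identical(rollup_level1("Ocular itching", dict), "itchy eyes")
  expect_identical(rollup_level1("Throat tightness", dict),
                   "Throat tightness")
  expect_error(rollup_level1("not in dict", dict), "dictionary")
})

test_that("the cascade is idempotent on matched output", {
  dict <- tiny_dict()
  inputs <- c("Nausea", "Throat tightness - Baseline Phase",
              "Cholecyctitis", "Eye itching")
  for (tm in inputs) {
    r1 <- normalize_ae(tm, dict)
    expect_true(r1$matched)
    r2 <- normalize_ae(r1$normalized_term, dict)
    expect_identical(r2$stage, 0L)
    expect_identical(r2$normalized_term, r1$normalized_term)
  }
})

test_that("event rows with variant terms merge into one rolled-up node", {
  dict <- tiny_dict()
  rows <- data.frame(
    nct_id = "NCT1", group_id = c("EG1", "EG2"),
    ae_term = c("Eye itching", "Ocular itching"),
    organ_system = "eye disorders",
    subjects_affected = c("1", "2"), subjects_at_risk = c("10", "12"))
  out <- build_adverse_event_nodes(rows, dict)
  expect_identical(nrow(out$ae_nodes), 1L)
  expect_identical(out$ae_nodes$term, "itchy eyes")
  expect_identical(nrow(out$group_ae_edges), 2L)
  expect_identical(out$group_ae_edges$subjects_affected, c("1", "2"))
  expect_identical(nrow(out$ae_organ_edges), 1L)
})

test_that("after roll-up no emitted node term is a level-1 dictionary term", {
  dict <- synthetic_hierarchy(20L)$dict
  set.seed(10)
  vars <- plant_ae_variants(dict, 80L, fixture_config())
  rows <- data.frame(nct_id = "NCT1", group_id = "EG1",
                     ae_term = vars$variant, organ_system = "x",
                     subjects_affected = "1", subjects_at_risk = "9")
  out <- build_adverse_event_nodes(rows, dict)
  levels_of <- dict$entries$level[match(tolower(out$ae_nodes$term),
                                        dict$entries$key)]
  expect_true(all(is.na(levels_of) | levels_of >= 2L))
})

test_that("unmatchable terms become nodes under their processed form", {
  dict <- tiny_dict()
  rows <- data.frame(nct_id = "N", group_id = "EG1",
                     ae_term = "zzqqy wwxxv", organ_system = "misc",
                     subjects_affected = "1", subjects_at_risk = "5")
  out <- build_adverse_event_nodes(rows, dict)
  expect_identical(out$ae_nodes$matched, "false")
  expect_identical(out$ae_nodes$term, "zzqqy wwxxv")
})

test_that("missing organ systems get the designated unknown organ", {
  dict <- tiny_dict()
  rows <- data.frame(nct_id = "N", group_id = "EG1", ae_term = "Nausea",
                     organ_system = NA, subjects_affected = "1",
                     subjects_at_risk = "5")
  expect_warning(out <- build_adverse_event_nodes(rows, dict), "unknown")
  expect_identical(out$ae_organ_edges$tail_id, "organ:unknown")
})

test_that("conflicting organ systems resolve to the majority organ", {
  dict <- tiny_dict()
  rows <- data.frame(
    nct_id = "N", group_id = c("EG1", "EG2", "EG3"), ae_term = "Nausea",
    organ_system = c("gastro", "gastro", "cardiac"),
    subjects_affected = "1", subjects_at_risk = "5")
  out <- build_adverse_event_nodes(rows, dict)
  expect_identical(nrow(out$ae_organ_edges), 1L)
  expect_identical(out$ae_organ_edges$tail_id, "organ:gastro")
})

test_that("an empty event table yields empty outputs", {
  out <- build_adverse_event_nodes(data.frame(), tiny_dict())
  expect_identical(nrow(out$ae_nodes), 0L)
  expect_identical(nrow(out$group_ae_edges), 0L)
})
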