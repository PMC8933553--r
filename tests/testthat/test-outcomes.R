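test_that("abbreviation-definition pairs are mined from titles", {
  p <- find_abbreviations("Gingival Health Measured by Bleeding Index (BI)")
  expect_identical(p$abbreviation, "BI")
  expect_identical(p$definition, "Bleeding Index")

  p <- find_abbreviations("changes in blood oxygenation level-dependent (BOLD)")
  expect_identical(p$abbreviation, "BOLD")
  expect_identical(p$definition, "blood oxygenation level-dependent")

  expect_identical(nrow(find_abbreviations("no abbreviations here")), 0L)
  # too long / no letters / too many words are not short forms
  expect_identical(nrow(find_abbreviations("x (12345)")), 0L)
  expect_identical(nrow(find_abbreviations(
    "some phrase (three word abbreviation)")), 0L)
  # multiple pairs come back left to right
  p <- find_abbreviations(
    "Visual Analogue Scale (VAS) and Bleeding Index (BI)")
  expect_identical(p$abbreviation, c("VAS", "BI"))
})

test_that("every mined pair satisfies the in-order matching invariant", {
  set.seed(19)
  words <- c("blood", "pressure", "bleeding", "index", "visual", "analogue",
             "scale", "quality", "life", "score", "forced", "expiratory",
             "volume", "total", "severity", "pain", "count", "platelet")
  for (i in 1:300) {
    n <- sample(3:7, 1)
    ws <- sample(words, n, replace = TRUE)
    abbr_n <- sample(2:4, 1)
    base <- sample(seq_len(max(1, n - abbr_n + 1)), 1)
    abbr <- toupper(paste(substr(ws[seq(base, min(n, base + abbr_n - 1))],
                                 1, 1), collapse = ""))
    title <- paste0(paste(ws, collapse = " "), " (", abbr, ")")
    pairs <- find_abbreviations(title)
    if (nrow(pairs)) for (j in seq_len(nrow(pairs)))
      expect_true(abbrev_pair_valid(pairs[j, ], title))
    # adversarial: random parenthetical that may not be an abbreviation
    title2 <- paste(paste(ws, collapse = " "),
                    sprintf("(%s)", sample(c("XQZ", "mild", "n=12"), 1)))
    pairs2 <- find_abbreviations(title2)
    if (nrow(pairs2)) for (j in seq_len(nrow(pairs2)))
      expect_true(abbrev_pair_valid(pairs2[j, ], title2))
  }
})

test_that("the keyword filter matches whole words only", {
  expect_true(is_standard_candidate("Visual Analogue Scale"))
  expect_true(is_standard_candidate("Bleeding Index"))
  expect_false(is_standard_candidate("Body Mass"))
  # hyphenation is a word boundary
  expect_true(is_standard_candidate("blood oxygenation level-dependent"))
  # keyword inside a longer word does not count
  expect_false(is_standard_candidate("upscaled"))
  expect_false(is_standard_candidate("ratescale"))
  set.seed(23)
  kw <- standard_outcome_keywords()
  fillers <- c("body", "mass", "change", "total", "severity")
  for (i in 1:100) {
    ws <- sample(c(kw, fillers), 4, replace = TRUE)
    s <- paste(ws, collapse = sample(c(" ", "-", ", "), 1))
    oracle <- any(tolower(ws) %in% kw)
    expect_identical(is_standard_candidate(s), oracle)
  }
})

test_that("standard-outcome nodes come from mined definitions plus manual additions", {
  oc <- data.frame(
    id = as.character(1:3),
    title = c("Gingival Health Measured by Bleeding Index (BI)",
              "Pain on the Visual Analogue Scale (VAS)",
              "Weight change"),
    description = c("", "", ""))
  std <- build_standard_outcomes(oc)
  expect_setequal(std$term, c("Bleeding Index", "Visual Analogue Scale"))

  std <- build_standard_outcomes(oc, manual_additions = "Overall Survival")
  expect_true("Overall Survival" %in% std$term)

  # variant overrides fold mined variants; dedupe is case-insensitive
  std <- build_standard_outcomes(
    oc, manual_additions = "bleeding index",
    variant_overrides = c("Visual Analogue Scale" = "Bleeding Index"))
  expect_identical(std$term, "Bleeding Index")

  expect_identical(nrow(build_standard_outcomes(oc[0, ])), 0L)
})

test_that("outcomes link to every standard their text contains", {
  oc <- data.frame(
    id = c("o1", "o2", "o3"),
    title = c("Change From Baseline in Platelet Count and White Blood Cell Count",
              "Nothing relevant", "Quality of life"),
    description = c("", "", "assessed by Platelet Count"))
  std <- data.table::data.table(
    node_id = c("standardoutcome:platelet count",
                "standardoutcome:white blood cell count"),
    term = c("Platelet Count", "White Blood Cell Count"))
  edges <- link_standard_outcomes(oc, std)
  expect_identical(sum(edges$head_id == "outcome:o1"), 2L)
  expect_identical(sum(edges$head_id == "outcome:o2"), 0L)
  # match in the description only still links
  expect_identical(edges$tail_id[edges$head_id == "outcome:o3"],
                   "standardoutcome:platelet count")
})
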