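# Seeded generator of registry-like trial tables, stand-in dictionaries and
# ground-truth maps. Fixtures exist to exercise every pipeline stage offline;
# they make no attempt at medical realism.

#' Configuration of the synthetic trial fixture
#'
#' Counts and variant rates of the generated registry snapshot. The defaults
#' describe the standing study conditions of the test fixtures: 30 studies of
#' which 4 lack drug interventions, 2 lack outcome analyses and 1 lacks
#' conditions (the three exclusion stages of the study filter); adverse-event
#' terms are reported as dictionary terms or as variants planted behind a
#' parenthetical, an auxiliary phrase, inserted stop words/inflection, or a
#' misspelling within edit distance 3 — each always recoverable by the
#' cascade by construction; a small rate of unmatchable gibberish terms
#' exercises the non-normalizable branch; drug mentions appear as brand,
#' generic or abbreviated surfaces.
#'
#' @param n_studies Total studies generated.
#' @param n_no_drug,n_no_analysis,n_no_condition Studies planted incomplete
#'   for each filter stage (in stage order).
#' @param n_conditions,n_drugs,n_ae_terms Vocabulary sizes (level-2
#'   adverse-event terms; each gets two level-1 children).
#' @param rate_parenthetical,rate_aux,rate_stopword,rate_misspell Rates of
#'   the four adverse-event variant kinds (remainder reported verbatim).
#' @param rate_unmatchable Rate of out-of-dictionary gibberish terms.
#' @param rate_brand,rate_abbrev Rates of brand / abbreviated drug surfaces
#'   (remainder generic).
#' @param n_outcome_topics Planted outcome-title topics.
#' @param seed Integer seed; generation is deterministic given the seed.
#' @return A list of class `fixture_config`.
#' @export
fixture_config <- function(n_studies = 30L, n_no_drug = 4L,
                           n_no_analysis = 2L, n_no_condition = 1L,
                           n_conditions = 10L, n_drugs = 8L,
                           n_ae_terms = 30L,
                           rate_parenthetical = 0.15, rate_aux = 0.2,
                           rate_stopword = 0.15, rate_misspell = 0.15,
                           rate_unmatchable = 0.05,
                           rate_brand = 0.3, rate_abbrev = 0.2,
                           n_outcome_topics = 4L, seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              n_no_drug = as.integer(n_no_drug),
              n_no_analysis = as.integer(n_no_analysis),
              n_no_condition = as.integer(n_no_condition),
              n_conditions = as.integer(n_conditions),
              n_drugs = as.integer(n_drugs),
              n_ae_terms = as.integer(n_ae_terms),
              rate_parenthetical = rate_parenthetical, rate_aux = rate_aux,
              rate_stopword = rate_stopword, rate_misspell = rate_misspell,
              rate_unmatchable = rate_unmatchable,
              rate_brand = rate_brand, rate_abbrev = rate_abbrev,
              n_outcome_topics = as.integer(n_outcome_topics),
              seed = as.integer(seed))
  rates <- unlist(cfg[grep("^rate_", names(cfg))])
  if (any(rates < 0 | rates > 1))
    stop("variant rates must lie in [0, 1]", call. = FALSE)
  if (rate_parenthetical + rate_aux + rate_stopword + rate_misspell +
      rate_unmatchable > 1)
    stop("adverse-event variant rates sum to more than 1", call. = FALSE)
  if (any(unlist(cfg[grep("^n_", names(cfg))]) < 0))
    stop("counts must be non-negative", call. = FALSE)
  n_incomplete <- cfg$n_no_drug + cfg$n_no_analysis + cfg$n_no_condition
  if (n_incomplete >= cfg$n_studies)
    stop("incomplete studies must leave at least one complete study",
         call. = FALSE)
  if (cfg$n_outcome_topics < 1L)
    stop("at least one outcome topic required", call. = FALSE)
  structure(cfg, class = "fixture_config")
}

# ---- vocabularies (fixed; sampled from deterministically) -----------------

fixture_bodies <- function() {
  c("throat", "knee", "eye", "chest", "back", "arm", "ear", "hip", "jaw",
    "ankle", "wrist", "shoulder", "neck", "elbow", "scalp")
}

fixture_symptoms <- function() {
  c("pain", "tightness", "rash", "spasm", "cramp", "ache", "numbness",
    "stiffness", "tremor", "ulcer", "swelling", "redness", "tenderness",
    "itch", "burning")
}

fixture_organs <- function() {
  c("musculoskeletal disorders", "skin disorders", "nervous system disorders",
    "eye disorders", "gastrointestinal disorders", "cardiac disorders",
    "respiratory disorders", "vascular disorders", "renal disorders",
    "immune system disorders", "hepatic disorders", "ear disorders",
    "endocrine disorders", "psychiatric disorders", "blood disorders")
}

fixture_conditions <- function(n) {
  base <- c("hypertension", "asthma", "migraine", "psoriasis",
            "osteoarthritis", "depression", "obesity", "anemia", "insomnia",
            "dermatitis", "rhinitis", "gastritis", "neuropathy", "glaucoma",
            "bronchitis", "colitis")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("condition %02d", seq_len(n - length(base))))
}

# statistical-method vocabulary; squashed forms pairwise far apart so the
# single-linkage merge can never bridge two different methods
fixture_methods <- function() {
  c("paired t-test", "analysis of covariance",
    "wilcoxon signed-rank test", "chi-squared test",
    "fisher exact test", "kruskal-wallis test",
    "log-rank test", "mixed effects model")
}

fixture_topics <- function(n) {
  pool <- list(
    list(noun = "Waist Circumference", words = c("waist", "circumference"),
         standard = "Waist Circumference Value", abbr = "WCV"),
    list(noun = "Blood Pressure", words = c("blood", "pressure"),
         standard = "Systolic Pressure Level", abbr = "SPL"),
    list(noun = "Gingival Health", words = c("gingival", "health"),
         standard = "Bleeding Index", abbr = "BI"),
    list(noun = "Reported Pain", words = c("reported", "pain"),
         standard = "Visual Analogue Scale", abbr = "VAS"),
    list(noun = "Sleep Quality", words = c("sleep", "quality"),
         standard = "Insomnia Severity Score", abbr = "ISS"),
    list(noun = "Lung Function", words = c("lung", "function"),
         standard = "Expiratory Volume Rate", abbr = "EVR"))
  if (n > length(pool))
    stop("at most ", length(pool), " outcome topics supported", call. = FALSE)
  pool[seq_len(n)]
}

# invented drug names: generic, brand, 3-letter abbreviation, tree code
fixture_drug_catalog <- function(n) {
  pre <- c("zo", "ma", "ke", "lu", "vi", "ra", "ne", "do", "fi", "ga",
           "be", "su")
  mid <- c("fa", "ri", "lo", "te", "mi", "pa", "ve", "no", "du", "sa",
           "ki", "bo")
  suf <- c("nib", "mab", "pril", "olol", "statin", "azole", "micin",
           "parin", "tadine", "xaban", "zepam", "fenac")
  if (n > length(suf)) stop("at most ", length(suf), " drugs supported",
                            call. = FALSE)
  pre <- pre[seq_len(n)]; mid <- rev(mid)[seq_len(n)]; suf <- suf[seq_len(n)]
  generic <- paste0(pre, mid, suf)
  brand <- paste0(toupper(substring(mid, 1, 1)), substring(mid, 2), pre, "ex")
  abbrev <- toupper(paste0(substring(generic, 1, 2), substring(suf, 1, 1)))
  canonical <- paste0(toupper(substring(generic, 1, 1)), substring(generic, 2))
  data.table::data.table(
    generic = generic, brand = brand, abbrev = abbrev, canonical = canonical,
    tree_code = sprintf("D02.%03d.%03d", seq_len(n), 100 + seq_len(n)))
}

# ---- adverse-event dictionary and variants --------------------------------

#' Synthetic adverse-event hierarchy
#'
#' Builds a two-level stand-in dictionary: `n` level-2 terms of the form
#' "body symptom", each with two level-1 children ("body symptom episode" /
#' "body symptom attack") that roll up to it, plus the organ system attached
#' to each term.
#'
#' @param n Number of level-2 terms.
#' @return A list: `dict` (a [term_hierarchy()]) and `organ_of` (named
#'   character vector, level-2 term -> organ system).
#' @export
synthetic_hierarchy <- function(n = 30L) {
  bodies <- fixture_bodies()
  symptoms <- fixture_symptoms()
  combos <- data.table::CJ(body = seq_along(bodies),
                           symptom = seq_along(symptoms), sorted = TRUE)
  if (n > nrow(combos)) stop("too many adverse-event terms requested",
                             call. = FALSE)
  combos <- combos[seq_len(n)]
  l2 <- paste(bodies[combos$body], symptoms[combos$symptom])
  organ_of <- stats::setNames(fixture_organs()[combos$body], l2)
  entries <- data.table::rbindlist(list(
    data.table::data.table(term = l2, level = 2L, parent = NA_character_),
    data.table::data.table(term = paste(l2, "episode"), level = 1L,
                           parent = l2),
    data.table::data.table(term = paste(l2, "attack"), level = 1L,
                           parent = l2)))
  list(dict = term_hierarchy(entries), organ_of = organ_of)
}

aux_decorations <- function() {
  c("Left %s", "Right %s", "%s - Baseline Phase", "%s for 12 hours",
    "%s for 2 weeks", "%s at 6 months")
}

parenthetical_decorations <- function() {
  c("%s (mild)", "%s (reported by investigator)", "%s (worst grade)",
    "%s (transient)")
}

# substitute 1-3 inner letters of a dictionary term, then verify against the
# whole dictionary that the cascade's view of the misspelling (its lemmatized
# form) still resolves uniquely to the planted term
misspell_term <- function(term, dict) {
  keys <- dict$entries$key
  simp <- dict$entries$simp
  tkey <- tolower(term)
  ti <- which(keys == tkey)
  for (attempt in 1:25) {
    n_edits <- sample.int(3L, 1L)
    chars <- strsplit(term, "", fixed = TRUE)[[1]]
    inner <- which(grepl("[a-z]", chars, ignore.case = TRUE))
    inner <- inner[inner > 1 & inner < length(chars)]
    if (length(inner) < n_edits) next
    pos <- sample(inner, n_edits)
    for (p in pos) {
      repl <- sample(setdiff(letters, tolower(chars[p])), 1L)
      chars[p] <- repl
    }
    cand <- paste(chars, collapse = "")
    ck <- simplify_tokens(tolower(cand))
    # an accidental earlier-stage hit must already point at the target
    if (ck %in% keys) { if (ck == tkey) return(cand) else next }
    hits <- tolower(dict$entries$term[simp == ck])
    if (length(hits)) { if (all(hits == tkey)) return(cand) else next }
    d_keys <- edit_distance_to(ck, keys)
    if (d_keys[ti] <= 3L &&
        (length(keys) == 1L || d_keys[ti] < min(d_keys[-ti])))
      return(cand)
  }
  NULL
}

# one AE variant of a given kind; returns list(text, kind)
make_ae_variant <- function(term, kind, dict) {
  switch(kind,
    exact = list(text = term, kind = "exact"),
    parenthetical = list(
      text = sprintf(sample(parenthetical_decorations(), 1L), term),
      kind = "parenthetical"),
    aux = list(text = sprintf(sample(aux_decorations(), 1L), term),
               kind = "aux"),
    stopword = {
      toks <- strsplit(term, " ", fixed = TRUE)[[1]]
      last <- toks[length(toks)]
      if (!grepl("(s|ss|us|is)$", last) && nchar(last) > 3L)
        toks[length(toks)] <- paste0(last, "s")
      list(text = paste("the", paste(toks, collapse = " ")),
           kind = "stopword")
    },
    misspell = {
      m <- misspell_term(term, dict)
      if (is.null(m)) list(text = term, kind = "exact")
      else list(text = m, kind = "misspell")
    },
    stop("unknown variant kind: ", kind))
}

#' Plant recoverable adverse-event variants
#'
#' Draws dictionary terms and wraps each in one of the cascade-recoverable
#' variant kinds (verbatim, parenthetical, auxiliary phrase, stop-word /
#' inflection, misspelling within edit distance 3) at the configured rates.
#' Every planted variant is recoverable by construction; misspellings are
#' verified at generation time to remain the strict nearest dictionary
#' neighbour. Used by the fixture generator and directly by recovery tests.
#'
#' @param dict A [term_hierarchy()] from [synthetic_hierarchy()].
#' @param n Number of variants.
#' @param cfg A [fixture_config()] supplying the rates.
#' @return A data.table: `variant`, `term` (the planted dictionary term),
#'   `canonical` (after level-1 roll-up), `kind`.
#' @export
plant_ae_variants <- function(dict, n, cfg = fixture_config()) {
  terms <- dict$entries$term
  kinds <- c("exact", "parenthetical", "aux", "stopword", "misspell")
  probs <- c(1 - cfg$rate_parenthetical - cfg$rate_aux - cfg$rate_stopword -
               cfg$rate_misspell - cfg$rate_unmatchable,
             cfg$rate_parenthetical, cfg$rate_aux, cfg$rate_stopword,
             cfg$rate_misspell)
  probs <- probs / sum(probs)
  rows <- lapply(seq_len(n), function(i) {
    tm <- sample(terms, 1L)
    v <- make_ae_variant(tm, sample(kinds, 1L, prob = probs), dict)
    data.table::data.table(variant = v$text, term = tm,
                           canonical = rollup_level1(tm, dict),
                           kind = v$kind)
  })
  data.table::rbindlist(rows)
}

# gibberish term at distance > 3 from every dictionary term
unmatchable_term <- function(dict) {
  keys <- dict$entries$key
  simp <- dict$entries$simp
  repeat {
    w1 <- paste(sample(c("q", "x", "z", "w", "v", "k", "j"), 5,
                       replace = TRUE), collapse = "")
    w2 <- paste(sample(c("q", "x", "z", "w", "v", "k", "j"), 6,
                       replace = TRUE), collapse = "")
    cand <- paste(w1, w2)
    if (min(edit_distance_to(cand, keys)) > 3L &&
        min(edit_distance_to(cand, simp)) > 3L)
      return(cand)
  }
}

# ---- generator ------------------------------------------------------------

#' Generate a synthetic registry snapshot with ground truth
#'
#' Emits the full set of trial tables the builder consumes, a stand-in
#' adverse-event hierarchy, a drug lexicon with abbreviations, and the
#' ground-truth maps tests need: which canonical term every planted variant
#' must recover to, which filter stage excludes each study, which topic each
#' outcome title belongs to, and the planted condition pair sharing drug
#' neighborhoods (with a held-out condition/drug pair for repurposing).
#' Byte-identical output for a fixed configuration.
#'
#' @param cfg A [fixture_config()].
#' @return A list of class `trial_fixture`: `tables` (a `trial_tables`),
#'   `dict`, `organ_of`, `lexicon`, `truth`, `config`.
#' @export
generate_fixture <- function(cfg = fixture_config()) {
  stopifnot(inherits(cfg, "fixture_config"))
  with_seed(cfg$seed, generate_fixture_impl(cfg))
}

generate_fixture_impl <- function(cfg) {
  hier <- synthetic_hierarchy(cfg$n_ae_terms)
  dict <- hier$dict
  organ_of <- hier$organ_of

  drugs <- fixture_drug_catalog(cfg$n_drugs)
  lex_entries <- data.table::rbindlist(list(
    drugs[, list(surface = generic, tree_code, canonical, generic)],
    drugs[, list(surface = brand, tree_code, canonical, generic)],
    # non-specific entries removed by the tree-code class filter
    data.table::data.table(surface = c("placebo mixture", "dose vehicle"),
                           tree_code = c("D26.310", "D26.255"),
                           canonical = c("placebo mixture", "dose vehicle"),
                           generic = NA_character_)))
  lex_entries <- filter_lexicon_codes(lex_entries)
  lexicon <- drug_lexicon(
    lex_entries,
    abbreviations = drugs[, list(abbreviation = abbrev, full_name = generic)])

  conditions <- fixture_conditions(cfg$n_conditions)
  methods <- fixture_methods()
  topics <- fixture_topics(cfg$n_outcome_topics)

  n <- cfg$n_studies
  ncts <- sprintf("NCT%08d", seq_len(n))
  flags <- rep("complete", n)
  if (cfg$n_no_drug) flags[seq_len(cfg$n_no_drug)] <- "no_drug"
  if (cfg$n_no_analysis)
    flags[cfg$n_no_drug + seq_len(cfg$n_no_analysis)] <- "no_analysis"
  if (cfg$n_no_condition)
    flags[cfg$n_no_drug + cfg$n_no_analysis +
            seq_len(cfg$n_no_condition)] <- "no_condition"
  complete <- which(flags == "complete")

  # planted embedding structure among the first complete studies: conditions
  # P1 and P2 are studied together in six studies (identical study and drug
  # neighborhoods {d1, d2}); drug d3 is studied only with P2 in two further
  # studies, so (P1, d3) is the held-out repurposing pair
  motif <- NULL
  if (length(complete) >= 8L && cfg$n_drugs >= 4L && cfg$n_conditions >= 3L) {
    motif <- list(c1 = conditions[1], c2 = conditions[2],
                  d12 = drugs$canonical[1:2], d3 = drugs$canonical[3],
                  studies = ncts[complete[1:8]])
  }

  tb <- list(studies = list(), interventions = list(), conditions = list(),
             result_groups = list(), reported_events = list(),
             outcomes = list(), outcome_measurements = list(),
             outcome_analyses = list(), outcome_analysis_groups = list(),
             drop_withdrawals = list(), milestones = list(),
             baseline_measurements = list())
  push <- function(tab, row) tb[[tab]][[length(tb[[tab]]) + 1L]] <<- row

  truth_ae <- list()
  truth_drug <- list()
  truth_method <- list()
  truth_topic <- list()
  out_counter <- 0L
  meas_counter <- 0L
  ana_counter <- 0L
  drop_counter <- 0L
  base_counter <- 0L

  drug_surface <- function(di) {
    u <- stats::runif(1)
    if (u < cfg$rate_brand) drugs$brand[di]
    else if (u < cfg$rate_brand + cfg$rate_abbrev) drugs$abbrev[di]
    else drugs$generic[di]
  }

  for (si in seq_len(n)) {
    nct <- ncts[si]
    flag <- flags[si]
    push("studies", data.table::data.table(
      nct_id = nct, title = sprintf("Study %03d", si),
      phase = sample(c("Phase 1", "Phase 2", "Phase 3"), 1L),
      status = "Completed",
      enrollment = as.character(sample(20:400, 1L))))

    # conditions (absent for the no_condition stage); studies outside the
    # planted motif avoid its conditions and drugs so the repurposing pair
    # stays un-co-studied and the shared neighborhood stays clean
    cond_pool <- if (is.null(motif)) conditions else conditions[-(1:2)]
    if (flag != "no_condition") {
      cond <- if (!is.null(motif) && nct %in% motif$studies) {
        if (match(nct, motif$studies) <= 6L) c(motif$c1, motif$c2)
        else motif$c2
      } else sample(cond_pool, sample(1:2, 1L))
      for (cd in unique(cond))
        push("conditions", data.table::data.table(nct_id = nct, name = cd))
    }

    # interventions (type Drug absent for the no_drug stage)
    if (flag == "no_drug") {
      push("interventions", data.table::data.table(
        nct_id = nct, type = "Procedure", name = "supervised exercise"))
      study_drugs <- integer(0)
    } else {
      drug_pool <- if (is.null(motif)) seq_len(cfg$n_drugs)
                   else setdiff(seq_len(cfg$n_drugs), 1:3)
      study_drugs <- if (!is.null(motif) && nct %in% motif$studies) {
        pos <- match(nct, motif$studies)
        if (pos <= 6L) 1:2 else 3L
      } else sample(drug_pool, sample(1:2, 1L))
      for (di in study_drugs) {
        surf <- drug_surface(di)
        push("interventions", data.table::data.table(
          nct_id = nct, type = "Drug",
          name = sprintf("%s %d Mg Oral Tablet", surf,
                         sample(c(5L, 10L, 25L, 50L), 1L))))
        truth_drug[[length(truth_drug) + 1L]] <- data.table::data.table(
          surface = surf, canonical = drugs$canonical[di])
      }
    }

    # result groups: two of each kind for complete studies, fewer otherwise
    n_groups <- if (flag == "complete") 2L else 1L
    eg_ids <- sprintf("EG%d", seq_len(n_groups))
    for (g in seq_len(n_groups)) {
      di <- if (length(study_drugs)) study_drugs[1 + (g - 1) %% length(study_drugs)] else NA
      gtitle <- if (!is.na(di))
        sprintf("%s %d mg", drug_surface(di), sample(c(5L, 10L, 25L), 1L))
      else "control arm"
      if (!is.na(di))
        truth_drug[[length(truth_drug) + 1L]] <- data.table::data.table(
          surface = sub(" .*", "", gtitle), canonical = drugs$canonical[di])
      gdesc <- "participants treated as randomized"
      # auxiliary drug mentioned only in an event-group description
      if (flag == "complete" && cfg$n_drugs >= 4L && g == 1L &&
          stats::runif(1) < 0.5) {
        aux_d <- cfg$n_drugs
        gdesc <- sprintf("participants treated as randomized; %s given as needed for pain",
                         drugs$generic[aux_d])
        truth_drug[[length(truth_drug) + 1L]] <- data.table::data.table(
          surface = drugs$generic[aux_d], canonical = drugs$canonical[aux_d])
      }
      push("result_groups", data.table::data.table(
        nct_id = nct, group_id = eg_ids[g], result_type = "Reported Event",
        title = gtitle, description = gdesc))
      push("result_groups", data.table::data.table(
        nct_id = nct, group_id = sprintf("BG%d", g), result_type = "Baseline",
        title = gtitle, description = "baseline characteristics"))
      push("result_groups", data.table::data.table(
        nct_id = nct, group_id = sprintf("PG%d", g),
        result_type = "Participant Flow", title = gtitle,
        description = "participant flow"))
      push("result_groups", data.table::data.table(
        nct_id = nct, group_id = sprintf("OG%d", g), result_type = "Outcome",
        title = gtitle, description = "analyzed population"))
    }

    # reported adverse events with planted variants
    for (g in seq_len(n_groups)) {
      n_ev <- sample(2:4, 1L)
      for (e in seq_len(n_ev)) {
        if (stats::runif(1) < cfg$rate_unmatchable) {
          vt <- unmatchable_term(dict)
          push("reported_events", data.table::data.table(
            nct_id = nct, group_id = eg_ids[g], ae_term = vt,
            organ_system = "unclassified disorders",
            subjects_affected = as.character(sample(0:20, 1L)),
            subjects_at_risk = as.character(sample(30:200, 1L))))
          truth_ae[[length(truth_ae) + 1L]] <- data.table::data.table(
            variant = vt, canonical = NA_character_, kind = "unmatchable")
        } else {
          pv <- plant_ae_variants(dict, 1L, cfg)
          push("reported_events", data.table::data.table(
            nct_id = nct, group_id = eg_ids[g], ae_term = pv$variant,
            organ_system = unname(organ_of[pv$canonical]),
            subjects_affected = as.character(sample(0:20, 1L)),
            subjects_at_risk = as.character(sample(30:200, 1L))))
          truth_ae[[length(truth_ae) + 1L]] <- data.table::data.table(
            variant = pv$variant, canonical = pv$canonical, kind = pv$kind)
        }
      }
    }

    # baseline records
    for (g in seq_len(n_groups)) {
      for (b in c("Age", "Weight")) {
        base_counter <- base_counter + 1L
        push("baseline_measurements", data.table::data.table(
          id = as.character(base_counter), nct_id = nct,
          group_id = sprintf("BG%d", g), title = b, category = "Mean",
          param_value = sprintf("%.1f", stats::runif(1, 20, 90))))
      }
    }

    # withdrawal chains
    for (g in seq_len(n_groups)) {
      periods <- c("First Intervention", "Follow-up")[seq_len(sample(1:2, 1L))]
      for (pi in seq_along(periods)) {
        push("milestones", data.table::data.table(
          nct_id = nct, group_id = sprintf("PG%d", g), period = periods[pi],
          order_index = as.character(pi),
          count = as.character(sample(10:100, 1L))))
        for (reason in sample(c("Adverse Event", "Withdrawal by Subject",
                                "Lost to Follow-up"), sample(1:2, 1L))) {
          drop_counter <- drop_counter + 1L
          push("drop_withdrawals", data.table::data.table(
            id = as.character(drop_counter), nct_id = nct,
            group_id = sprintf("PG%d", g), period = periods[pi],
            reason = reason, count = as.character(sample(0:8, 1L))))
        }
      }
    }

    # outcomes, measurements, analyses
    n_out <- if (flag == "complete") sample(2:4, 1L) else 1L
    for (o in seq_len(n_out)) {
      out_counter <- out_counter + 1L
      oid <- as.character(out_counter)
      tp <- sample(seq_along(topics), 1L)
      topic <- topics[[tp]]
      style <- sample(1:3, 1L)
      title <- switch(style,
        sprintf("Change From Baseline in %s", topic$noun),
        sprintf("%s Measured by %s (%s)", topic$noun, topic$standard,
                topic$abbr),
        sprintf("Mean %s at Week %d", topic$noun, sample(c(4L, 12L, 24L), 1L)))
      push("outcomes", data.table::data.table(
        id = oid, nct_id = nct, title = title,
        description = sprintf("Assessment of %s using %s (%s).",
                              tolower(topic$noun), topic$standard,
                              topic$abbr)))
      truth_topic[[length(truth_topic) + 1L]] <- data.table::data.table(
        outcome_id = oid, topic = tp)

      for (g in seq_len(n_groups)) {
        meas_counter <- meas_counter + 1L
        push("outcome_measurements", data.table::data.table(
          id = as.character(meas_counter), outcome_id = oid, nct_id = nct,
          group_id = sprintf("OG%d", g), category = "Mean",
          value = sprintf("%.2f", stats::rnorm(1)),
          dispersion = sprintf("%.2f", stats::runif(1, 0.1, 2))))
      }

      if (flag != "no_analysis") {
        for (a in seq_len(sample(1:2, 1L))) {
          ana_counter <- ana_counter + 1L
          base_method <- sample(methods, 1L)
          mv <- method_variant(base_method)
          truth_method[[length(truth_method) + 1L]] <- data.table::data.table(
            variant = mv, canonical = base_method)
          push("outcome_analyses", data.table::data.table(
            id = as.character(ana_counter), outcome_id = oid, nct_id = nct,
            method = mv,
            p_value = sprintf("%.4f", stats::runif(1))))
          for (g in seq_len(n_groups))
            push("outcome_analysis_groups", data.table::data.table(
              analysis_id = as.character(ana_counter), nct_id = nct,
              group_id = sprintf("OG%d", g)))
        }
      }
    }
  }

  tables <- structure(
    lapply(tb, function(rows) if (length(rows)) data.table::rbindlist(rows)
           else data.table::data.table()),
    class = "trial_tables")

  truth <- list(
    ae = unique(data.table::rbindlist(truth_ae)),
    drug = unique(data.table::rbindlist(truth_drug)),
    method = unique(data.table::rbindlist(truth_method)),
    outcome_topic = data.table::rbindlist(truth_topic),
    study_flags = stats::setNames(flags, ncts),
    motif = motif)

  structure(list(tables = tables, dict = dict, organ_of = organ_of,
                 lexicon = lexicon, truth = truth, config = cfg),
            class = "trial_fixture")
}

# frequency-skewed method-name variants: the base spelling dominates, so it
# is always the highest-count member of its merged component
method_variant <- function(base) {
  u <- stats::runif(1)
  if (u < 0.6) return(base)
  if (u < 0.75) return(gsub("-", " ", base))
  if (u < 0.85) return(paste0(base, "s"))
  if (u < 0.95) {
    toks <- strsplit(base, " ", fixed = TRUE)[[1]]
    if (length(toks) > 1L)
      return(paste(c(toks[length(toks)], toks[-length(toks)]),
                   collapse = ", "))
    return(base)
  }
  # single inner-letter misspelling
  chars <- strsplit(base, "", fixed = TRUE)[[1]]
  inner <- which(grepl("[a-z]", chars))
  inner <- inner[inner > 1 & inner < length(chars)]
  p <- sample(inner, 1L)
  chars[p] <- sample(setdiff(letters, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Write a fixture's inputs to disk
#'
#' Writes the trial tables, the hierarchy and lexicon dictionaries, and the
#' ground-truth maps as tab-separated files under `dir` (tables in
#' `dir/tables`, dictionaries and truth files at the top level), the layout
#' the command-line pipeline consumes.
#'
#' @param fx A `trial_fixture` from [generate_fixture()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  stopifnot(inherits(fx, "trial_fixture"))
  dir.create(file.path(dir, "tables"), recursive = TRUE, showWarnings = FALSE)
  write_trial_tables(fx$tables, file.path(dir, "tables"))
  write_term_hierarchy(fx$dict, file.path(dir, "ae_hierarchy.tsv"))
  data.table::fwrite(fx$lexicon$entries[, list(surface, tree_code, canonical,
                                               generic)],
                     file.path(dir, "drug_lexicon.tsv"), sep = "\t",
                     quote = "auto", na = "")
  data.table::fwrite(fx$lexicon$abbreviations[, list(abbreviation, full_name)],
                     file.path(dir, "drug_abbreviations.tsv"), sep = "\t",
                     quote = "auto", na = "")
  data.table::fwrite(fx$truth$ae, file.path(dir, "truth_ae.tsv"),
                     sep = "\t", quote = "auto", na = "")
  data.table::fwrite(fx$truth$drug, file.path(dir, "truth_drug.tsv"),
                     sep = "\t", quote = "auto", na = "")
  data.table::fwrite(fx$truth$method, file.path(dir, "truth_method.tsv"),
                     sep = "\t", quote = "auto", na = "")
  invisible(dir)
}
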