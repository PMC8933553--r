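# Small hand-built fixtures shared by unit tests.

tiny_dict <- function() {
  term_hierarchy(data.frame(
    term = c("itchy eyes", "Eye itching", "Ocular itching",
             "Throat tightness", "Cholecystitis", "Altered pitch perception",
             "knee pain", "Nausea"),
    level = c(2L, 1L, 1L, 2L, 2L, 2L, 2L, 2L),
    parent = c(NA, "itchy eyes", "itchy eyes", NA, NA, NA, NA, NA)))
}

tiny_lexicon <- function() {
  drug_lexicon(
    data.frame(
      surface = c("losartan", "losartan potassium", "cozaar", "naltrexone",
                  "tramadol", "diclofenac", "telaprevir", "ibuprofen"),
      tree_code = c("D02.001", "D02.001", "D02.001", "D02.002", "D02.003",
                    "D02.004", "D02.005", "D02.241.223.701.430"),
      canonical = c("losartan", "losartan", "losartan", "Naltrexone",
                    "Tramadol", "Diclofenac", "Telaprevir", "Ibuprofen"),
      generic = c("losartan", "losartan", "losartan", "naltrexone",
                  "tramadol", "diclofenac", "telaprevir", "ibuprofen")),
    abbreviations = data.frame(abbreviation = c("tvr", "umec"),
                               full_name = c("Telaprevir", "Umeclidinium")))
}

# a minimal valid graph: 2 studies, 3 conditions, one event group chain
tiny_kg <- function() {
  kg <- kg_new()
  kg <- kg_add_nodes(kg, "Study", data.frame(
    node_id = c("study:NCT1", "study:NCT2"), nct_id = c("NCT1", "NCT2")))
  kg <- kg_add_nodes(kg, "Condition", data.frame(
    node_id = paste0("condition:c", 1:3), term = paste0("c", 1:3)))
  kg <- kg_add_edges(kg, "Study-Condition",
                     c("study:NCT1", "study:NCT1", "study:NCT1", "study:NCT2"),
                     c("condition:c1", "condition:c2", "condition:c3",
                       "condition:c1"))
  kg <- kg_add_nodes(kg, "EventGroup", data.frame(
    node_id = "eventgroup:NCT1:EG1", nct_id = "NCT1", title = "arm A"))
  kg <- kg_add_edges(kg, "Study-EventGroup", "study:NCT1",
                     "eventgroup:NCT1:EG1")
  kg <- kg_add_nodes(kg, "AdverseEvent", data.frame(
    node_id = "adverseevent:nausea", term = "Nausea"))
  kg <- kg_add_nodes(kg, "Organ", data.frame(
    node_id = "organ:gastro", organ_system = "gastro"))
  kg <- kg_add_edges(kg, "EventGroup-AdverseEvent", "eventgroup:NCT1:EG1",
                     "adverseevent:nausea")
  kg <- kg_add_edges(kg, "AdverseEvent-Organ", "adverseevent:nausea",
                     "organ:gastro")
  kg
}

# ten hand-built studies exercising the three filter stages: 4 lack drug
# interventions, 2 (of the rest) lack analyses, 1 (of the rest) lacks
# conditions, 3 complete
filter_fixture_tables <- function() {
  ncts <- sprintf("S%02d", 1:10)
  tabs <- list(
    studies = data.frame(nct_id = ncts, title = ncts),
    interventions = data.frame(
      nct_id = ncts,
      type = c(rep("Device", 4), rep("Drug", 6)),
      name = "x"),
    outcome_analyses = data.frame(
      nct_id = ncts[c(1:4, 7:10)], id = as.character(1:8),
      outcome_id = "1", method = "t-test", p_value = "0.05"),
    conditions = data.frame(nct_id = ncts[c(1:6, 8:10)], name = "asthma"))
  for (nm in setdiff(trial_table_names(), names(tabs)))
    tabs[[nm]] <- data.frame()
  structure(tabs[trial_table_names()], class = "trial_tables")
}

# minimal complete single-study tables for the assemble hand count
minimal_tables <- function() {
  tabs <- list(
    studies = data.frame(nct_id = "NCT1", title = "t", phase = "Phase 2"),
    interventions = data.frame(nct_id = "NCT1", type = "Drug",
                               name = "Naltrexone 50 Mg Oral Tablet"),
    conditions = data.frame(nct_id = "NCT1", name = "depression"),
    result_groups = data.frame(
      nct_id = "NCT1", group_id = c("EG1", "OG1"),
      result_type = c("Reported Event", "Outcome"),
      title = c("Naltrexone arm", "Naltrexone arm"),
      description = c("treated", "analyzed")),
    reported_events = data.frame(
      nct_id = "NCT1", group_id = "EG1", ae_term = "Nausea",
      organ_system = "gastrointestinal disorders",
      subjects_affected = "2", subjects_at_risk = "20"),
    outcomes = data.frame(id = "1", nct_id = "NCT1",
                          title = "Change in mood", description = "d"),
    outcome_measurements = data.frame(
      id = "1", outcome_id = "1", nct_id = "NCT1", group_id = "OG1",
      category = "Mean", value = "1.2", dispersion = "0.3"),
    outcome_analyses = data.frame(
      id = "1", outcome_id = "1", nct_id = "NCT1", method = "paired t-test",
      p_value = "0.002"),
    outcome_analysis_groups = data.frame(analysis_id = "1", nct_id = "NCT1",
                                         group_id = "OG1"))
  for (nm in setdiff(trial_table_names(), names(tabs)))
    tabs[[nm]] <- data.frame()
  structure(tabs[trial_table_names()], class = "trial_tables")
}
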