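#' Graph schema for clinical-trial knowledge graphs
#'
#' The default schema declares the 18 node types and 21 relation types of the
#' trial knowledge graph: studies link to conditions, drug terms, outcomes and
#' four kinds of participant groups (event, baseline, drop, outcome); adverse
#' events roll up to organ systems; outcome analyses reference statistical
#' methods; outcomes link to standard outcome measures and to title clusters.
#'
#' Each relation carries a cardinality class on each endpoint:
#' \describe{
#'   \item{`one`}{every node of that type carries exactly one edge of this
#'     relation (e.g. every event group belongs to exactly one study);}
#'   \item{`at_most_one`}{zero or one edge (e.g. an outcome analysis names at
#'     most one method);}
#'   \item{`many`}{unconstrained.}
#' }
#' Cardinality classes are derived from the per-relation unique-head /
#' unique-tail counts published for the released graph: a relation whose edge
#' count equals the node count of an endpoint type is `one`; one with fewer
#' participating nodes than exist of the type is `at_most_one`.
#'
#' @return An object of class `trial_schema`: a list with data.tables
#'   `node_types` (`node_type`, `study_specific`) and `relations`
#'   (`relation`, `head_type`, `tail_type`, `head_card`, `tail_card`).
#' @examples
#' sch <- trial_schema()
#' nrow(sch$node_types)  # 18
#' nrow(sch$relations)   # 21
#' @export
trial_schema <- function() {
  node_types <- data.table::data.table(
    node_type = c(
      "Study", "Condition", "DrugTerm", "EventGroup", "AdverseEvent", "Organ",
      "BaselineGroup", "BaselineRecord", "DropGroup", "Period", "DropRecord",
      "OutcomeGroup", "Method", "OutcomeMeasurement", "OutcomeAnalysis",
      "Outcome", "StandardOutcome", "ClusterOutcome"),
    study_specific = c(
      TRUE, FALSE, FALSE, TRUE, FALSE, FALSE,
      TRUE, TRUE, TRUE, TRUE, TRUE,
      TRUE, FALSE, TRUE, TRUE,
      TRUE, FALSE, FALSE)
  )
  rel <- function(relation, head_type, tail_type, head_card, tail_card)
    list(relation, head_type, tail_type, head_card, tail_card)
  relations <- data.table::rbindlist(list(
    rel("Study-Condition",                 "Study", "Condition",     "many", "many"),
    rel("Study-EventGroup",                "Study", "EventGroup",    "many", "one"),
    rel("Study-BaselineGroup",             "Study", "BaselineGroup", "many", "one"),
    rel("Study-DropGroup",                 "Study", "DropGroup",     "many", "one"),
    rel("Study-OutcomeGroup",              "Study", "OutcomeGroup",  "many", "one"),
    rel("Study-Outcome",                   "Study", "Outcome",       "many", "one"),
    rel("Study-StudiedDrug",               "Study", "DrugTerm",      "many", "many"),
    rel("Study-UsedDrug",                  "Study", "DrugTerm",      "many", "many"),
    rel("Drug-EventGroup",                 "DrugTerm", "EventGroup", "many", "many"),
    rel("EventGroup-AdverseEvent",         "EventGroup", "AdverseEvent", "many", "many"),
    rel("AdverseEvent-Organ",              "AdverseEvent", "Organ",  "one",  "many"),
    rel("BaselineGroup-BaselineRecord",    "BaselineGroup", "BaselineRecord", "many", "one"),
    rel("DropGroup-Period",                "DropGroup", "Period",    "many", "one"),
    rel("Period-DropRecord",               "Period", "DropRecord",   "many", "one"),
    rel("OutcomeGroup-OutcomeMeasurement", "OutcomeGroup", "OutcomeMeasurement", "many", "at_most_one"),
    rel("OutcomeGroup-OutcomeAnalysis",    "OutcomeGroup", "OutcomeAnalysis", "many", "many"),
    rel("OutcomeAnalysis-Method",          "OutcomeAnalysis", "Method", "at_most_one", "many"),
    rel("Outcome-OutcomeAnalysis",         "Outcome", "OutcomeAnalysis", "many", "one"),
    rel("Outcome-OutcomeMeasurement",      "Outcome", "OutcomeMeasurement", "many", "one"),
    rel("Outcome-ClusterOutcome",          "Outcome", "ClusterOutcome", "at_most_one", "many"),
    rel("Outcome-StandardOutcome",         "Outcome", "StandardOutcome", "many", "many")
  ))
  data.table::setnames(relations, c("relation", "head_type", "tail_type",
                                    "head_card", "tail_card"))
  new_trial_schema(node_types, relations)
}

new_trial_schema <- function(node_types, relations) {
  node_types <- data.table::as.data.table(node_types)
  relations <- data.table::as.data.table(relations)
  bad <- setdiff(c(relations$head_type, relations$tail_type),
                 node_types$node_type)
  if (length(bad))
    stop("relation endpoint type(s) not declared as node types: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (anyDuplicated(node_types$node_type))
    stop("duplicate node type in schema", call. = FALSE)
  if (anyDuplicated(relations$relation))
    stop("duplicate relation type in schema", call. = FALSE)
  cards <- c("one", "at_most_one", "many")
  if (!all(relations$head_card %in% cards) ||
      !all(relations$tail_card %in% cards))
    stop("cardinality class must be one of: ", paste(cards, collapse = ", "),
         call. = FALSE)
  structure(list(node_types = node_types, relations = relations),
            class = "trial_schema")
}

#' Read or write a graph schema as a declarative JSON config
#'
#' The schema (node types, study-specific flags, relations with endpoint types
#' and cardinality classes) round-trips through a plain JSON file so the
#' relation set can be extended without touching code.
#'
#' @param path Path of the JSON config file.
#' @return `read_schema()` returns a `trial_schema`; `write_schema()` returns
#'   `path` invisibly.
#' @seealso [trial_schema()] for the default schema.
#' @export
read_schema <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_trial_schema(data.table::as.data.table(cfg$node_types),
                   data.table::as.data.table(cfg$relations))
}

#' @rdname read_schema
#' @param schema A `trial_schema` object.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "trial_schema"))
  jsonlite::write_json(
    list(node_types = schema$node_types, relations = schema$relations),
    path, dataframe = "rows", auto_unbox = FALSE, pretty = TRUE)
  invisible(path)
}

#' @export
print.trial_schema <- function(x, ...) {
  cat(sprintf("<trial_schema> %d node types, %d relation types\n",
              nrow(x$node_types), nrow(x$relations)))
  invisible(x)
}
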