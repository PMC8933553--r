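trial_table_names <- function() {
  c("studies", "interventions", "conditions", "result_groups",
    "reported_events", "outcomes", "outcome_measurements",
    "outcome_analyses", "outcome_analysis_groups", "drop_withdrawals",
    "milestones", "baseline_measurements")
}

#' Read registry-style trial tables from a directory
#'
#' Loads the delimited text tables the builder consumes (a documented subset
#' of a registry's public relational schema): `studies`, `interventions`,
#' `conditions`, `result_groups`, `reported_events`, `outcomes`,
#' `outcome_measurements`, `outcome_analyses`, `outcome_analysis_groups`,
#' `drop_withdrawals`, `milestones`, `baseline_measurements`, each as
#' `<name>.tsv`. Missing files become empty tables. All columns are read as
#' text.
#'
#' @param dir Directory containing the `.tsv` files.
#' @return A named list of data.tables of class `trial_tables`.
#' @export
read_trial_tables <- function(dir) {
  if (!dir.exists(dir)) stop("table directory not found: ", dir, call. = FALSE)
  tabs <- lapply(trial_table_names(), function(nm) {
    f <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(f) || file.size(f) == 0)
      return(data.table::data.table())
    data.table::fread(f, sep = "\t", header = TRUE, colClasses = "character",
                      na.strings = "")
  })
  names(tabs) <- trial_table_names()
  structure(tabs, class = "trial_tables")
}

#' Write trial tables to a directory
#' @param tables A `trial_tables` list.
#' @param dir Output directory (created if absent).
#' @export
write_trial_tables <- function(tables, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(tables))
    data.table::fwrite(tables[[nm]], file.path(dir, paste0(nm, ".tsv")),
                       sep = "\t", quote = "auto", na = "")
  invisible(dir)
}

#' Filter studies to those with drug interventions, analyses and conditions
#'
#' Applies the three-stage exclusion cascade in fixed order: (1) studies with
#' no intervention of type "Drug", (2) studies with no outcome-analysis rows,
#' (3) studies with no condition rows. Stage counts are order-dependent and
#' reported per stage; kept + excluded always sums to the input count.
#'
#' @param tables A `trial_tables` list.
#' @return A list of class `filter_outcome`: `kept` (character vector of
#'   study ids), `excluded` (named integer vector with stages
#'   `no_drug_intervention`, `no_outcome_analysis`, `no_condition`),
#'   `n_input`.
#' @export
filter_studies <- function(tables) {
  st <- data.table::as.data.table(tables$studies)
  ids <- sort(unique(as.character(st$nct_id)))
  n_input <- length(ids)
  has_drug <- unique(with(data.table::as.data.table(tables$interventions),
                          nct_id[tolower(type) == "drug"]))
  s1 <- ids[ids %in% has_drug]
  x1 <- n_input - length(s1)
  has_analysis <- unique(as.character(
    data.table::as.data.table(tables$outcome_analyses)$nct_id))
  s2 <- s1[s1 %in% has_analysis]
  x2 <- length(s1) - length(s2)
  has_condition <- unique(as.character(
    data.table::as.data.table(tables$conditions)$nct_id))
  s3 <- s2[s2 %in% has_condition]
  x3 <- length(s2) - length(s3)
  structure(list(kept = s3,
                 excluded = c(no_drug_intervention = x1,
                              no_outcome_analysis = x2,
                              no_condition = x3),
                 n_input = n_input),
            class = "filter_outcome")
}

#' @export
print.filter_outcome <- function(x, ...) {
  cat(sprintf(
    "<filter_outcome> %d studies in; excluded %d (no drug intervention), %d (no outcome analysis), %d (no condition); kept %d\n",
    x$n_input, x$excluded[[1]], x$excluded[[2]], x$excluded[[3]],
    length(x$kept)))
  invisible(x)
}

#' Configuration for graph assembly
#'
#' @param clusters Number of outcome-title clusters (`NULL` = min(200,
#'   number of outcomes), the released graph's cluster count capped by the
#'   corpus size).
#' @param seed Integer seed for the clustering restarts.
#' @param pats Auxiliary-phrase patterns for the adverse-event cascade.
#' @param ae_overrides,drug_overrides,method_overrides Optional named
#'   character vectors of curation overrides (raw form = name, forced
#'   canonical = value).
#' @param manual_standards Character vector of manually added standard
#'   outcome measures.
#' @param standard_variant_overrides Named character vector folding mined
#'   standard-outcome variants to canonical names.
#' @param standard_keywords Keyword filter; default
#'   [standard_outcome_keywords()].
#' @return A list of class `assemble_config`.
#' @export
assemble_config <- function(clusters = NULL, seed = 1L,
                            pats = default_phrase_patterns(),
                            ae_overrides = NULL, drug_overrides = NULL,
                            method_overrides = NULL,
                            manual_standards = character(0),
                            standard_variant_overrides = NULL,
                            standard_keywords = standard_outcome_keywords()) {
  structure(list(clusters = clusters, seed = as.integer(seed), pats = pats,
                 ae_overrides = ae_overrides, drug_overrides = drug_overrides,
                 method_overrides = method_overrides,
                 manual_standards = manual_standards,
                 standard_variant_overrides = standard_variant_overrides,
                 standard_keywords = standard_keywords),
            class = "assemble_config")
}

group_node_id <- function(result_type, nct_id, group_id) {
  prefix <- c("reported event" = "eventgroup", "baseline" = "baselinegroup",
              "participant flow" = "dropgroup", "outcome" = "outcomegroup")
  p <- prefix[tolower(result_type)]
  ifelse(is.na(p), NA_character_, paste0(p, ":", nct_id, ":", group_id))
}

#' Assemble the knowledge graph from filtered trial tables
#'
#' Runs the full construction: study filter, condition and group nodes,
#' adverse-event normalization with organ roll-up, drug-mention tagging and
#' studied/used classification, withdrawal (drop) chains, baseline records,
#' outcome / measurement / analysis nodes with canonicalized statistical
#' methods, standard-outcome extraction and linking, and outcome-title
#' clustering. Input rows that reference a missing parent (study, group,
#' outcome) are skipped with a warning. The assembled graph satisfies every
#' schema invariant checked by [validate_graph()].
#'
#' @param tables A `trial_tables` list.
#' @param dict A [term_hierarchy()] for adverse-event normalization.
#' @param lex A [drug_lexicon()] for drug-mention tagging.
#' @param config An [assemble_config()].
#' @return A `trial_kg`. Assembly by-products (the `filter_outcome`, the
#'   outcome-cluster report, the method canonicalization map, the
#'   adverse-event cascade table) are attached as `kg$meta`.
#' @export
assemble <- function(tables, dict, lex, config = assemble_config()) {
  stopifnot(inherits(config, "assemble_config"))
  fo <- filter_studies(tables)
  kept <- fo$kept
  kg <- kg_new(trial_schema())
  meta <- list(filter = fo)
  if (!length(kept)) { kg$meta <- meta; return(kg) }

  sub <- function(tab) {
    dt <- data.table::as.data.table(tab)
    if (!nrow(dt)) return(dt)
    dt[nct_id %in% kept]
  }

  st <- sub(tables$studies)
  study_attrs <- st[, intersect(c("nct_id", "title", "phase", "status",
                                  "enrollment"), names(st)), with = FALSE]
  kg <- kg_add_nodes(kg, "Study",
                     cbind(data.table::data.table(
                       node_id = paste0("study:", st$nct_id)), study_attrs))

  co <- sub(tables$conditions)
  if (nrow(co)) {
    co[, key := tolower(trimws(name))]
    data.table::setorder(co, key, name)
    cn <- co[!duplicated(key), list(node_id = paste0("condition:", key),
                                    term = name)]
    kg <- kg_add_nodes(kg, "Condition", cn)
    pairs <- unique(co[, list(nct_id, key)])
    kg <- kg_add_edges(kg, "Study-Condition",
                       paste0("study:", pairs$nct_id),
                       paste0("condition:", pairs$key))
  }

  gr <- sub(tables$result_groups)
  group_ids <- character(0)
  if (nrow(gr)) {
    gr[, node_id := group_node_id(result_type, nct_id, group_id)]
    bad <- is.na(gr$node_id)
    if (any(bad)) {
      warning(sum(bad), " result-group row(s) with unknown result_type skipped",
              call. = FALSE)
      gr <- gr[!bad]
    }
    gr <- gr[!duplicated(node_id)]
    group_ids <- gr$node_id
    type_map <- c("reported event" = "EventGroup", "baseline" = "BaselineGroup",
                  "participant flow" = "DropGroup", "outcome" = "OutcomeGroup")
    gr[, node_type := type_map[tolower(result_type)]]
    for (ty in unique(gr$node_type)) {
      g <- gr[node_type == ty]
      kg <- kg_add_nodes(kg, ty, g[, list(node_id, nct_id, title, description)])
      kg <- kg_add_edges(kg, paste0("Study-", ty),
                         paste0("study:", g$nct_id), g$node_id)
    }
  }

  ev <- sub(tables$reported_events)
  if (nrow(ev)) {
    ev[, eg := paste0("eventgroup:", nct_id, ":", group_id)]
    orphan <- !(ev$eg %in% group_ids)
    if (any(orphan)) {
      warning(sum(orphan),
              " reported-event row(s) referencing a missing event group skipped",
              call. = FALSE)
      ev <- ev[!orphan]
    }
  }
  if (nrow(ev)) {
    ae <- build_adverse_event_nodes(ev, dict, config$pats, config$ae_overrides)
    kg <- kg_add_nodes(kg, "AdverseEvent", ae$ae_nodes)
    kg <- kg_add_nodes(kg, "Organ", ae$organ_nodes)
    kg <- kg_add_edges(kg, "EventGroup-AdverseEvent",
                       ae$group_ae_edges$head_id, ae$group_ae_edges$tail_id,
                       attrs = ae$group_ae_edges[, list(subjects_affected,
                                                        subjects_at_risk)])
    kg <- kg_add_edges(kg, "AdverseEvent-Organ",
                       ae$ae_organ_edges$head_id, ae$ae_organ_edges$tail_id)
    meta$ae_cascade <- ae$cascade
  }

  mentions <- collect_drug_mentions(sub(tables$interventions),
                                    if (nrow(gr)) gr else NULL,
                                    lex, config$drug_overrides)
  drugs <- assign_drug_edges(mentions)
  if (nrow(drugs$drug_nodes)) {
    kg <- kg_add_nodes(kg, "DrugTerm", drugs$drug_nodes)
    kg <- kg_add_edges(kg, "Study-StudiedDrug",
                       drugs$studied_edges$head_id, drugs$studied_edges$tail_id)
    kg <- kg_add_edges(kg, "Study-UsedDrug",
                       drugs$used_edges$head_id, drugs$used_edges$tail_id)
    deg <- drugs$drug_eventgroup_edges
    deg <- deg[tail_id %in% group_ids]
    kg <- kg_add_edges(kg, "Drug-EventGroup", deg$head_id, deg$tail_id)
    meta$drug_mentions <- mentions
  }

  dw <- sub(tables$drop_withdrawals)
  ms <- sub(tables$milestones)
  drop_ids <- group_ids[startsWith(group_ids, "dropgroup:")]
  if (nrow(dw)) {
    dw[, dg := paste0("dropgroup:", nct_id, ":", group_id)]
    orphan <- !(dw$dg %in% drop_ids)
    if (any(orphan)) {
      warning(sum(orphan),
              " withdrawal row(s) referencing a missing drop group skipped",
              call. = FALSE)
      dw <- dw[!orphan]
    }
  }
  if (nrow(ms)) {
    ms[, dg := paste0("dropgroup:", nct_id, ":", group_id)]
    ms <- ms[dg %in% drop_ids]
  }
  per <- data.table::rbindlist(list(
    if (nrow(ms)) ms[, list(nct_id, group_id, period,
                            order_index = if ("order_index" %in% names(ms))
                              order_index else NA_character_)],
    if (nrow(dw)) dw[, list(nct_id, group_id, period,
                            order_index = NA_character_)]),
    use.names = TRUE)
  if (!is.null(per) && nrow(per)) {
    per <- per[order(nct_id, group_id,
                     suppressWarnings(as.numeric(order_index)))]
    per <- per[!duplicated(per[, list(nct_id, group_id, period)])]
    per[, node_id := paste0("period:", nct_id, ":", group_id, ":",
                            tolower(gsub("[^[:alnum:]]+", "_", period)))]
    kg <- kg_add_nodes(kg, "Period",
                       per[, list(node_id, nct_id, title = period,
                                  order_index)])
    kg <- kg_add_edges(kg, "DropGroup-Period",
                       paste0("dropgroup:", per$nct_id, ":", per$group_id),
                       per$node_id)
    if (nrow(dw)) {
      dw[, period_id := paste0("period:", nct_id, ":", group_id, ":",
                               tolower(gsub("[^[:alnum:]]+", "_", period)))]
      dw[, node_id := paste0("droprecord:", id)]
      kg <- kg_add_nodes(kg, "DropRecord",
                         dw[, list(node_id, nct_id, reason, count)])
      kg <- kg_add_edges(kg, "Period-DropRecord", dw$period_id, dw$node_id)
    }
  }

  bm <- sub(tables$baseline_measurements)
  if (nrow(bm)) {
    bm[, bg := paste0("baselinegroup:", nct_id, ":", group_id)]
    orphan <- !(bm$bg %in% group_ids)
    if (any(orphan)) {
      warning(sum(orphan),
              " baseline row(s) referencing a missing baseline group skipped",
              call. = FALSE)
      bm <- bm[!orphan]
    }
    if (nrow(bm)) {
      bm[, node_id := paste0("baselinerecord:", id)]
      kg <- kg_add_nodes(kg, "BaselineRecord",
                         bm[, list(node_id, nct_id, title, category,
                                   param_value)])
      kg <- kg_add_edges(kg, "BaselineGroup-BaselineRecord", bm$bg, bm$node_id)
    }
  }

  oc <- sub(tables$outcomes)
  if (nrow(oc)) {
    oc[, node_id := paste0("outcome:", id)]
    kg <- kg_add_nodes(kg, "Outcome",
                       oc[, list(node_id, nct_id, title, description)])
    kg <- kg_add_edges(kg, "Study-Outcome",
                       paste0("study:", oc$nct_id), oc$node_id)
  }

  om <- sub(tables$outcome_measurements)
  if (nrow(om)) {
    orphan <- !(om$outcome_id %in% oc$id)
    if (any(orphan)) {
      warning(sum(orphan),
              " measurement row(s) referencing a missing outcome skipped",
              call. = FALSE)
      om <- om[!orphan]
    }
    if (nrow(om)) {
      om[, node_id := paste0("outcomemeasurement:", id)]
      keepcols <- intersect(c("node_id", "nct_id", "category", "value",
                              "dispersion"), names(om))
      kg <- kg_add_nodes(kg, "OutcomeMeasurement", om[, keepcols, with = FALSE])
      kg <- kg_add_edges(kg, "Outcome-OutcomeMeasurement",
                         paste0("outcome:", om$outcome_id), om$node_id)
      og <- paste0("outcomegroup:", om$nct_id, ":", om$group_id)
      has_g <- og %in% group_ids
      kg <- kg_add_edges(kg, "OutcomeGroup-OutcomeMeasurement",
                         og[has_g], om$node_id[has_g])
    }
  }

  oa <- sub(tables$outcome_analyses)
  if (nrow(oa)) {
    orphan <- !(oa$outcome_id %in% oc$id)
    if (any(orphan)) {
      warning(sum(orphan),
              " analysis row(s) referencing a missing outcome skipped",
              call. = FALSE)
      oa <- oa[!orphan]
    }
  }
  if (nrow(oa)) {
    oa[, node_id := paste0("outcomeanalysis:", id)]
    keepcols <- intersect(c("node_id", "nct_id", "method", "p_value",
                            "param_type"), names(oa))
    kg <- kg_add_nodes(kg, "OutcomeAnalysis", oa[, keepcols, with = FALSE])
    kg <- kg_add_edges(kg, "Outcome-OutcomeAnalysis",
                       paste0("outcome:", oa$outcome_id), oa$node_id)

    oag <- sub(tables$outcome_analysis_groups)
    if (nrow(oag)) {
      oag <- oag[analysis_id %in% oa$id]
      og <- paste0("outcomegroup:", oag$nct_id, ":", oag$group_id)
      has_g <- og %in% group_ids
      kg <- kg_add_edges(kg, "OutcomeGroup-OutcomeAnalysis",
                         og[has_g],
                         paste0("outcomeanalysis:", oag$analysis_id[has_g]))
    }

    with_method <- oa[!is.na(method) & nzchar(trimws(method))]
    if (nrow(with_method)) {
      counts <- table(with_method$method)
      method_map <- canonicalize_methods(
        stats::setNames(as.integer(counts), names(counts)),
        overrides = config$method_overrides)
      meta$method_map <- method_map
      canon <- unique(unname(method_map))
      mn <- data.table::data.table(node_id = paste0("method:", squash(canon)),
                                   term = canon)
      mn <- mn[!duplicated(node_id)]
      data.table::setorder(mn, node_id)
      kg <- kg_add_nodes(kg, "Method", mn)
      kg <- kg_add_edges(kg, "OutcomeAnalysis-Method",
                         with_method$node_id,
                         paste0("method:",
                                squash(method_map[with_method$method])))
    }
  }

  if (nrow(oc)) {
    standards <- build_standard_outcomes(
      oc, keywords = config$standard_keywords,
      manual_additions = config$manual_standards,
      variant_overrides = config$standard_variant_overrides)
    if (nrow(standards)) {
      kg <- kg_add_nodes(kg, "StandardOutcome", standards)
      so_edges <- link_standard_outcomes(oc, standards)
      kg <- kg_add_edges(kg, "Outcome-StandardOutcome",
                         so_edges$head_id, so_edges$tail_id)
    }

    k <- config$clusters %||% min(200L, nrow(oc))
    report <- cluster_outcomes(oc$title, k = k, seed = config$seed,
                               ids = oc$node_id)
    meta$cluster_report <- report
    ctab <- cluster_report_table(report)
    kg <- kg_add_nodes(kg, "ClusterOutcome", data.table::data.table(
      node_id = paste0("clusteroutcome:", ctab$cluster_id),
      size = as.character(ctab$size),
      descriptive = ctab$descriptive,
      discriminating = ctab$discriminating))
    kg <- kg_add_edges(kg, "Outcome-ClusterOutcome",
                       names(report$assignment),
                       paste0("clusteroutcome:", unname(report$assignment)))
  }

  kg$meta <- meta
  kg
}
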