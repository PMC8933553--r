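#' Leveled adverse-event term hierarchy
#'
#' A dictionary of adverse-event terms, each assigned a hierarchical level
#' (1 = most specific reporting term, up to 5) and, for level-1 terms, a
#' parent term at level 2. Term comparison throughout is case-insensitive
#' after whitespace trimming. Stands in for a licensed regulatory terminology,
#' which cannot be redistributed; the packaged fixtures use a synthetic
#' hierarchy with the same shape.
#'
#' @param entries A data.frame with columns `term`, `level` (integer 1-5) and
#'   `parent` (term or `NA`).
#' @param file A three-column tab-separated file (`term`, `level`, `parent`)
#'   read when `entries` is missing.
#' @return An object of class `term_hierarchy`.
#' @export
term_hierarchy <- function(entries = NULL, file = NULL) {
  if (is.null(entries)) {
    stopifnot(!is.null(file))
    entries <- data.table::fread(file, sep = "\t", header = TRUE,
                                 colClasses = "character", na.strings = "")
  }
  entries <- data.table::as.data.table(entries)
  stopifnot(all(c("term", "level", "parent") %in% names(entries)))
  entries <- entries[, list(term = as.character(term),
                            level = as.integer(level),
                            parent = as.character(parent))]
  entries[, key := tolower(trimws(term))]
  if (anyDuplicated(entries$key))
    stop("duplicate terms in hierarchy (case-insensitive)", call. = FALSE)
  key_set <- entries$key
  l1 <- entries[level == 1L]
  if (nrow(l1)) {
    bad <- l1[is.na(parent) | !(tolower(trimws(parent)) %in% key_set)]
    if (nrow(bad))
      stop("level-1 term(s) without a dictionary parent: ",
           paste(utils::head(bad$term, 5), collapse = ", "), call. = FALSE)
    pk <- tolower(trimws(l1$parent))
    plev <- entries$level[match(pk, entries$key)]
    if (any(plev != 2L))
      stop("level-1 term(s) whose parent is not level 2", call. = FALSE)
  }
  # pre-computed simplified index used by stage 3 of the cascade
  entries[, simp := simplify_tokens(term)]
  structure(list(entries = entries), class = "term_hierarchy")
}

#' @rdname term_hierarchy
#' @param x Object to test.
#' @export
is_term_hierarchy <- function(x) inherits(x, "term_hierarchy")

hier_lookup <- function(dict, terms) {
  dict$entries[match(tolower(trimws(terms)), dict$entries$key), ]
}

#' Write a term hierarchy to a tab-separated file
#' @param dict A `term_hierarchy`.
#' @param path Output file path.
#' @export
write_term_hierarchy <- function(dict, path) {
  data.table::fwrite(dict$entries[, list(term, level, parent)], path,
                     sep = "\t", quote = "auto", na = "")
  invisible(path)
}

#' Normalize one adverse-event term against a dictionary
#'
#' Applies the five-stage cascade, stopping at the first stage whose output is
#' a dictionary term (case-insensitive):
#' \describe{
#'   \item{stage 0}{direct lookup of the trimmed term;}
#'   \item{stage 1}{after stripping parenthesized content
#'     ([strip_parenthetical()]);}
#'   \item{stage 2}{after removing auxiliary/time-frame phrases
#'     ([remove_phrases()]);}
#'   \item{stage 3}{after stop-word removal and lemmatization
#'     ([simplify_tokens()]); the simplified form is also compared against the
#'     simplified dictionary terms, so "the Throat tightnesses" still resolves;}
#'   \item{stage 4}{edit-distance rescue — the nearest dictionary term at
#'     Levenshtein distance at most 3, ties broken by smaller distance then
#'     lexicographically smallest term; corrects simple misspellings such as
#'     "Cholecyctitis" to "Cholecystitis".}
#' }
#' Stages are cumulative: each operates on the previous stage's output. If no
#' stage matches, the result keeps the fully processed term with
#' `matched = FALSE`.
#'
#' @param term A single non-empty adverse-event term.
#' @param dict A [term_hierarchy()].
#' @param pats A [phrase_patterns()] list for stage 2; default
#'   [default_phrase_patterns()].
#' @param overrides Optional named character vector (names = raw terms,
#'   values = forced canonical terms) applied before the cascade; reproduces
#'   a manual curation pass.
#' @return A list of class `ae_cascade_result` with fields `input_term`,
#'   `normalized_term`, `matched`, `stage` (0-4, or `NA` when unmatched).
#' @export
normalize_ae <- function(term, dict, pats = default_phrase_patterns(),
                         overrides = NULL) {
  stop_if_not_scalar_chr(term, "term")
  if (!nzchar(trimws(term)))
    stop("empty adverse-event term: invalid record", call. = FALSE)
  stopifnot(is_term_hierarchy(dict))
  if (!nrow(dict$entries)) stop("empty dictionary", call. = FALSE)

  res <- function(normalized, matched, stage)
    structure(list(input_term = term, normalized_term = normalized,
                   matched = matched, stage = stage),
              class = "ae_cascade_result")

  if (!is.null(overrides)) {
    ov <- overrides[tolower(trimws(term)) == tolower(trimws(names(overrides)))]
    if (length(ov)) {
      forced <- unname(ov[[1]])
      hit <- hier_lookup(dict, forced)
      return(res(if (!is.na(hit$term)) hit$term else forced,
                 !is.na(hit$term), 0L))
    }
  }

  hit <- hier_lookup(dict, term)
  if (!is.na(hit$term)) return(res(hit$term, TRUE, 0L))

  s1 <- strip_parenthetical(term)
  hit <- hier_lookup(dict, s1)
  if (!is.na(hit$term)) return(res(hit$term, TRUE, 1L))

  s2 <- remove_phrases(s1, pats)
  hit <- hier_lookup(dict, s2)
  if (!is.na(hit$term)) return(res(hit$term, TRUE, 2L))

  s3 <- simplify_tokens(s2)
  hit <- hier_lookup(dict, s3)
  if (!is.na(hit$term)) return(res(hit$term, TRUE, 3L))
  cand <- dict$entries$term[dict$entries$simp == s3]
  if (length(cand)) return(res(sort(cand)[1], TRUE, 3L))

  if (nzchar(s3)) {
    keys <- dict$entries$key
    near <- keys[abs(nchar(keys) - nchar(s3)) <= 3L]
    if (length(near)) {
      d <- edit_distance_to(s3, near)
      if (min(d) <= 3L) {
        best <- dict$entries$term[match(near[d == min(d)], dict$entries$key)]
        return(res(sort(best)[1], TRUE, 4L))
      }
    }
  }
  res(s3, FALSE, NA_integer_)
}

#' Roll a level-1 dictionary term up to its level-2 parent
#'
#' Level-1 terms are the fine-grained reporting variants; several of them
#' ("Eye itching", "Ocular itching") share one level-2 parent ("itchy eyes")
#' that names the underlying event. Rolling up makes the event-to-node mapping
#' one-to-one. Terms at level 2 or higher are returned unchanged.
#'
#' @param term A dictionary term (error if absent).
#' @param dict A [term_hierarchy()].
#' @return The level-2 parent term if `term` is level 1, else `term` itself
#'   (in its dictionary display form).
#' @export
rollup_level1 <- function(term, dict) {
  stopifnot(is_term_hierarchy(dict))
  hit <- hier_lookup(dict, term)
  if (is.na(hit$term))
    stop("not a dictionary term: ", term, call. = FALSE)
  if (identical(hit$level, 1L)) {
    parent <- hier_lookup(dict, hit$parent)
    return(parent$term)
  }
  hit$term
}

# cascade + roll-up over unique raw terms; memoized table
normalize_ae_table <- function(terms, dict, pats = default_phrase_patterns(),
                               overrides = NULL) {
  uniq <- unique(terms)
  rows <- lapply(uniq, function(tm) {
    r <- normalize_ae(tm, dict, pats, overrides)
    final <- if (r$matched) rollup_level1(r$normalized_term, dict)
             else r$normalized_term
    data.table::data.table(input_term = tm, normalized_term = r$normalized_term,
                           matched = r$matched, stage = r$stage,
                           final_term = final)
  })
  data.table::rbindlist(rows)
}

#' Build adverse-event nodes and edges from reported-event rows
#'
#' Runs the normalization cascade plus level-1 roll-up over every distinct
#' raw term, producing one `AdverseEvent` node per distinct final term, one
#' `Organ` node per organ system observed, an event-group edge per input row
#' (carrying the per-group affected / at-risk counts as edge attributes), and
#' exactly one organ edge per adverse-event node. When a term is reported
#' under different organ systems, the majority organ wins, ties broken
#' lexicographically. Rows with a missing organ system are assigned the
#' designated `"unknown"` organ with a warning.
#'
#' @param event_rows A data.frame with columns `nct_id`, `group_id`,
#'   `ae_term`, `organ_system`, `subjects_affected`, `subjects_at_risk`.
#' @param dict A [term_hierarchy()].
#' @param pats A [phrase_patterns()] list; default
#'   [default_phrase_patterns()].
#' @param overrides Optional curation overrides, as in [normalize_ae()].
#' @return A list with data.tables `ae_nodes`, `organ_nodes`,
#'   `group_ae_edges` (head = event-group node id), `ae_organ_edges`, and the
#'   per-raw-term `cascade` table.
#' @export
build_adverse_event_nodes <- function(event_rows, dict,
                                      pats = default_phrase_patterns(),
                                      overrides = NULL) {
  ev <- data.table::as.data.table(event_rows)
  empty <- list(
    ae_nodes = data.table::data.table(node_id = character(0), term = character(0),
                                      matched = character(0), stage = character(0)),
    organ_nodes = data.table::data.table(node_id = character(0),
                                         organ_system = character(0)),
    group_ae_edges = data.table::data.table(head_id = character(0),
                                            tail_id = character(0),
                                            subjects_affected = character(0),
                                            subjects_at_risk = character(0)),
    ae_organ_edges = data.table::data.table(head_id = character(0),
                                            tail_id = character(0)),
    cascade = data.table::data.table())
  if (!nrow(ev)) return(empty)

  casc <- normalize_ae_table(ev$ae_term, dict, pats, overrides)
  ev <- merge(ev, casc, by.x = "ae_term", by.y = "input_term", sort = FALSE)
  ev[, ae_id := paste0("adverseevent:", tolower(final_term))]

  organ <- as.character(ev$organ_system)
  missing_organ <- is.na(organ) | !nzchar(trimws(organ))
  if (any(missing_organ)) {
    warning(sum(missing_organ), " reported-event row(s) without an organ ",
            "system; assigned organ 'unknown'", call. = FALSE)
    organ[missing_organ] <- "unknown"
  }
  ev[, organ_clean := organ]

  # majority organ per adverse-event node, ties lexicographically smallest
  org_pick <- ev[, list(n = .N), by = list(ae_id, organ_clean)]
  data.table::setorder(org_pick, ae_id, -n, organ_clean)
  org_pick <- org_pick[!duplicated(ae_id)]

  node_info <- ev[!duplicated(ae_id),
                  list(ae_id, final_term, matched, stage)]
  ae_nodes <- node_info[, list(
    node_id = ae_id, term = final_term,
    matched = ifelse(matched, "true", "false"),
    stage = as.character(stage))]

  organ_nodes <- data.table::data.table(
    organ_system = sort(unique(org_pick$organ_clean)))
  organ_nodes[, node_id := paste0("organ:", tolower(organ_system))]
  data.table::setcolorder(organ_nodes, c("node_id", "organ_system"))

  group_ae_edges <- ev[, list(
    head_id = paste0("eventgroup:", nct_id, ":", group_id),
    tail_id = ae_id,
    subjects_affected = as.character(subjects_affected),
    subjects_at_risk = as.character(subjects_at_risk))]

  ae_organ_edges <- org_pick[, list(
    head_id = ae_id, tail_id = paste0("organ:", tolower(organ_clean)))]

  list(ae_nodes = ae_nodes, organ_nodes = organ_nodes,
       group_ae_edges = group_ae_edges, ae_organ_edges = ae_organ_edges,
       cascade = casc)
}
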