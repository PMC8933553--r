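#' Drug lexicon for mention tagging and canonicalization
#'
#' Maps drug surface forms (generic names, brand names, salts) to a
#' hierarchical tree code and a canonical vocabulary term, with an auxiliary
#' abbreviation table (abbreviation to full name). Stands in for an external
#' medical-text-indexing service: tagging is deterministic dictionary
#' matching, and a curation-override file reproduces any manual pass.
#'
#' @param entries A data.frame with columns `surface`, `tree_code` (dotted
#'   code or `NA`), `canonical`, `generic` (or `NA`).
#' @param abbreviations Optional data.frame with columns `abbreviation`,
#'   `full_name`.
#' @param file,abbrev_file Tab-separated files read when the data.frames are
#'   missing.
#' @return An object of class `drug_lexicon`.
#' @export
drug_lexicon <- function(entries = NULL, abbreviations = NULL,
                         file = NULL, abbrev_file = NULL) {
  if (is.null(entries)) {
    stopifnot(!is.null(file))
    entries <- data.table::fread(file, sep = "\t", header = TRUE,
                                 colClasses = "character", na.strings = "")
  }
  entries <- data.table::as.data.table(entries)
  stopifnot(all(c("surface", "canonical") %in% names(entries)))
  if (!"tree_code" %in% names(entries)) entries[, tree_code := NA_character_]
  if (!"generic" %in% names(entries)) entries[, generic := NA_character_]
  entries <- entries[, list(surface = as.character(surface),
                            tree_code = as.character(tree_code),
                            canonical = as.character(canonical),
                            generic = as.character(generic))]
  entries[, key := tolower(trimws(surface))]
  if (anyDuplicated(entries$key))
    stop("duplicate surface forms in lexicon (case-insensitive)", call. = FALSE)
  if (any(is.na(entries$canonical) | !nzchar(entries$canonical)))
    stop("lexicon canonical terms must be non-empty", call. = FALSE)
  if (is.null(abbreviations) && !is.null(abbrev_file))
    abbreviations <- data.table::fread(abbrev_file, sep = "\t", header = TRUE,
                                       colClasses = "character",
                                       na.strings = "")
  if (is.null(abbreviations))
    abbreviations <- data.table::data.table(abbreviation = character(0),
                                            full_name = character(0))
  abbreviations <- data.table::as.data.table(abbreviations)
  stopifnot(all(c("abbreviation", "full_name") %in% names(abbreviations)))
  abbreviations[, key := tolower(trimws(abbreviation))]
  structure(list(entries = entries, abbreviations = abbreviations),
            class = "drug_lexicon")
}

#' @rdname drug_lexicon
#' @param x Object to test.
#' @export
is_drug_lexicon <- function(x) inherits(x, "drug_lexicon")

#' Does a hierarchical tree code denote a specific drug?
#'
#' Tree codes are dotted paths in a chemicals-and-drugs vocabulary; the "D"
#' branch holds drugs. Codes equal to, or dotted descendants of, the
#' non-specific classes D26 (pharmaceutical preparations), D26.310 (drug
#' combinations), D26.255 (dosage forms) and D23.101 (biomarkers) are
#' excluded because they do not name a specific drug.
#'
#' @param code Character vector of dotted tree codes.
#' @return Logical vector: `TRUE` iff the code's first segment starts with
#'   "D" and the code is outside the excluded subtrees.
#' @examples
#' is_drug_code("D02.241.223.701.430")  # TRUE (ibuprofen)
#' is_drug_code("D26.310")              # FALSE (drug combination)
#' is_drug_code("C01.252")              # FALSE (not a drug branch)
#' @export
is_drug_code <- function(code) {
  code <- trimws(as.character(code))
  excluded <- c("D26.310", "D26", "D23.101", "D26.255")
  vapply(code, function(cd) {
    if (is.na(cd) || !nzchar(cd)) return(FALSE)
    if (!startsWith(strsplit(cd, ".", fixed = TRUE)[[1]][1], "D")) return(FALSE)
    !any(cd == excluded | startsWith(cd, paste0(excluded, ".")))
  }, logical(1), USE.NAMES = FALSE)
}

#' Drop lexicon entries whose tree code is not a specific drug
#'
#' Applies [is_drug_code()] to a raw lexicon table (e.g. the output of an
#' entity tagger): entries carrying a tree code outside the drug branch or
#' inside the excluded non-specific classes are removed. Entries without a
#' tree code are kept (they correspond to manually curated drugs).
#'
#' @param entries A lexicon entry data.frame (see [drug_lexicon()]).
#' @return The filtered data.table.
#' @export
filter_lexicon_codes <- function(entries) {
  e <- data.table::as.data.table(entries)
  has_code <- !is.na(e$tree_code) & nzchar(trimws(e$tree_code))
  e[!has_code | is_drug_code(tree_code)]
}

#' Tag drug mentions in free text
#'
#' Scans text left to right for lexicon surface forms (including known
#' abbreviations), case-insensitively and
#' at word boundaries (a boundary is any non-alphanumeric character, so
#' "tramadol/diclofenac 25/25" yields both drugs). At each position the
#' longest matching surface form wins and the scan resumes after it, so
#' matches never overlap.
#'
#' @param text A single character string.
#' @param lex A [drug_lexicon()].
#' @return A data.table with one row per mention: `surface` (as written),
#'   `start`, `end` (character positions).
#' @export
tag_mentions <- function(text, lex) {
  stop_if_not_scalar_chr(text, "text")
  stopifnot(is_drug_lexicon(lex))
  surfaces <- c(lex$entries$surface, lex$abbreviations$abbreviation)
  out <- data.table::data.table(surface = character(0), start = integer(0),
                                end = integer(0))
  if (!length(surfaces) || !nzchar(text)) return(out)
  hits <- list()
  for (s in surfaces) {
    rx <- paste0("(?<![[:alnum:]])",
                 gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", s, perl = TRUE),
                 "(?![[:alnum:]])")
    m <- gregexpr(rx, text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    hits[[length(hits) + 1L]] <- data.table::data.table(
      start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
  }
  if (!length(hits)) return(out)
  cand <- data.table::rbindlist(hits)
  data.table::setorder(cand, start, -end)
  taken_until <- 0L
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (cand$start[i] > taken_until) {
      keep[i] <- TRUE
      taken_until <- cand$end[i]
    }
  }
  cand <- cand[keep]
  cand[, surface := substring(text, start, end)]
  data.table::setcolorder(cand, c("surface", "start", "end"))
  cand[]
}

#' Canonicalize a drug mention
#'
#' Resolution order: a curation override, if given; else expand a known
#' abbreviation to its full name; then the lexicon canonical term of the
#' (possibly expanded) form; then its generic name; finally the surface form
#' itself — the rule that keeps investigational-drug identifiers (e.g.
#' "pf-06669571") as their own canonical terms.
#'
#' @param surface Character vector of mention surface forms.
#' @param lex A [drug_lexicon()].
#' @param overrides Optional named character vector (names = surface forms,
#'   values = forced canonical terms).
#' @return Character vector of canonical terms.
#' @examples
#' \dontrun{normalize_mention("cozaar", lex)  # "losartan"}
#' @export
normalize_mention <- function(surface, lex, overrides = NULL) {
  stopifnot(is_drug_lexicon(lex))
  vapply(as.character(surface), function(s) {
    k <- tolower(trimws(s))
    if (!is.null(overrides)) {
      i <- match(k, tolower(trimws(names(overrides))))
      if (!is.na(i)) return(unname(overrides[[i]]))
    }
    ab <- match(k, lex$abbreviations$key)
    if (!is.na(ab)) {
      s <- lex$abbreviations$full_name[ab]
      k <- tolower(trimws(s))
    }
    i <- match(k, lex$entries$key)
    if (!is.na(i)) {
      e <- lex$entries[i, ]
      if (!is.na(e$canonical) && nzchar(e$canonical)) return(e$canonical)
      if (!is.na(e$generic) && nzchar(e$generic)) return(e$generic)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

#' Collect drug mentions from interventions and study groups
#'
#' Tags and canonicalizes drug mentions in drug-type intervention names and
#' in the titles and descriptions of result groups. Interventions whose name
#' yields no lexicon match contribute the whole trimmed name as an
#' investigational-drug mention (reproducing the identifier-as-term rule).
#'
#' @param interventions data.frame with columns `nct_id`, `type`, `name`.
#' @param groups data.frame with columns `nct_id`, `group_id`, `result_type`,
#'   `title`, `description`; may be `NULL`.
#' @param lex A [drug_lexicon()].
#' @param overrides Optional curation overrides, as in [normalize_mention()].
#' @return A data.table of mentions: `nct_id`, `source` (intervention /
#'   group_title / group_description), `group_id` (`NA` for interventions),
#'   `group_type`, `surface`, `canonical`.
#' @export
collect_drug_mentions <- function(interventions, groups, lex,
                                  overrides = NULL) {
  iv <- data.table::as.data.table(interventions)
  rows <- list()
  push <- function(nct, src, gid, gtype, surface) {
    rows[[length(rows) + 1L]] <<- data.table::data.table(
      nct_id = nct, source = src, group_id = gid, group_type = gtype,
      surface = surface)
  }
  iv <- iv[tolower(type) == "drug"]
  for (i in seq_len(nrow(iv))) {
    m <- tag_mentions(iv$name[i], lex)
    if (nrow(m)) {
      for (s in m$surface)
        push(iv$nct_id[i], "intervention", NA_character_, NA_character_, s)
    } else {
      # no lexicon hit: treat the whole name as an investigational identifier
      nm <- trimws(iv$name[i])
      if (nzchar(nm))
        push(iv$nct_id[i], "intervention", NA_character_, NA_character_, nm)
    }
  }
  if (!is.null(groups)) {
    gr <- data.table::as.data.table(groups)
    for (i in seq_len(nrow(gr))) {
      for (field in c("title", "description")) {
        txt <- gr[[field]][i]
        if (is.na(txt) || !nzchar(txt)) next
        m <- tag_mentions(txt, lex)
        if (nrow(m)) for (s in m$surface)
          push(gr$nct_id[i], paste0("group_", field), gr$group_id[i],
               gr$result_type[i], s)
      }
    }
  }
  if (!length(rows))
    return(data.table::data.table(nct_id = character(0), source = character(0),
                                  group_id = character(0),
                                  group_type = character(0),
                                  surface = character(0),
                                  canonical = character(0)))
  out <- data.table::rbindlist(rows)
  out[, canonical := normalize_mention(surface, lex, overrides)]
  out[]
}

#' Assign drug nodes and study/drug edges from canonicalized mentions
#'
#' Creates one `DrugTerm` node per canonical term and classifies each
#' (study, term) pair as either studied or merely used:
#' \itemize{
#'   \item a term mentioned in a drug intervention record or in the *title*
#'     of a result group (an arm-defining context) is a studied drug;
#'   \item a term mentioned for the study only in group *descriptions*
#'     (free-text context, e.g. an as-needed pain reducer) is a used drug.
#' }
#' The two edge sets are disjoint per study: studied wins. Mentions sourced
#' from event groups additionally yield drug/event-group edges.
#'
#' @param mentions A data.table from [collect_drug_mentions()].
#' @return A list with data.tables `drug_nodes`, `studied_edges`,
#'   `used_edges` (head = study node id, tail = drug node id) and
#'   `drug_eventgroup_edges` (head = drug node id, tail = event-group id).
#' @export
assign_drug_edges <- function(mentions) {
  m <- data.table::as.data.table(mentions)
  empty <- list(
    drug_nodes = data.table::data.table(node_id = character(0),
                                        term = character(0)),
    studied_edges = data.table::data.table(head_id = character(0),
                                           tail_id = character(0)),
    used_edges = data.table::data.table(head_id = character(0),
                                        tail_id = character(0)),
    drug_eventgroup_edges = data.table::data.table(head_id = character(0),
                                                   tail_id = character(0)))
  if (!nrow(m)) return(empty)
  m[, drug_id := paste0("drugterm:", tolower(canonical))]

  drug_nodes <- m[!duplicated(drug_id), list(node_id = drug_id,
                                             term = canonical)]
  data.table::setorder(drug_nodes, node_id)

  arm <- m[source == "intervention" | source == "group_title"]
  studied <- unique(arm[, list(nct_id, drug_id)])
  pairs <- unique(m[, list(nct_id, drug_id)])
  used <- pairs[!studied, on = c("nct_id", "drug_id")]

  studied_edges <- studied[, list(head_id = paste0("study:", nct_id),
                                  tail_id = drug_id)]
  used_edges <- used[, list(head_id = paste0("study:", nct_id),
                            tail_id = drug_id)]

  eg <- m[!is.na(group_id) & !is.na(group_type) &
            tolower(group_type) == "reported event"]
  deg <- unique(eg[, list(drug_id, nct_id, group_id)])
  drug_eventgroup_edges <- deg[, list(
    head_id = drug_id,
    tail_id = paste0("eventgroup:", nct_id, ":", group_id))]

  list(drug_nodes = drug_nodes, studied_edges = studied_edges,
       used_edges = used_edges,
       drug_eventgroup_edges = drug_eventgroup_edges)
}
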