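#' Find abbreviation-definition pairs in text (Schwartz-Hearst)
#'
#' Scans for parenthesized short forms and pairs each with its long-form
#' definition in the preceding text, using the Schwartz-Hearst candidate
#' rules. A short-form candidate has at most 2 words, at most 10 characters,
#' contains a letter, and starts with an alphanumeric character. The long
#' form is searched right-to-left through at most `min(|A| + 5, 2|A|)` words
#' before the parenthesis (|A| = short-form length) such that every
#' short-form character matches in order, case-insensitively, and the first
#' character matches at a word start.
#'
#' @param t A single character string.
#' @return A data.table with one row per pair: `abbreviation`, `definition`,
#'   `short_start`, `short_end`, `long_start`, `long_end` (character
#'   positions in `t`), ordered left to right.
#' @examples
#' find_abbreviations("Gingival Health Measured by Bleeding Index (BI)")
#' @export
find_abbreviations <- function(t) {
  stop_if_not_scalar_chr(t, "t")
  out <- data.table::data.table(abbreviation = character(0),
                                definition = character(0),
                                short_start = integer(0),
                                short_end = integer(0),
                                long_start = integer(0),
                                long_end = integer(0))
  m <- gregexpr("\\(([^()]*)\\)", t)[[1]]
  if (m[1] == -1L) return(out)
  for (i in seq_along(m)) {
    open <- as.integer(m[i])
    close <- open + attr(m, "match.length")[i] - 1L
    short <- substring(t, open + 1L, close - 1L)
    if (!valid_short_form(short)) next
    pre <- substring(t, 1L, open - 1L)
    lf <- best_long_form(short, pre)
    if (is.null(lf)) next
    out <- data.table::rbindlist(list(out, data.table::data.table(
      abbreviation = short, definition = lf$text,
      short_start = open + 1L, short_end = close - 1L,
      long_start = lf$start, long_end = lf$end)))
  }
  out
}

valid_short_form <- function(s) {
  s <- trimws(s)
  if (!nzchar(s) || nchar(s) > 10L) return(FALSE)
  if (length(strsplit(s, "[[:space:]]+")[[1]]) > 2L) return(FALSE)
  if (!grepl("[[:alpha:]]", s)) return(FALSE)
  grepl("^[[:alnum:]]", s)
}

# right-to-left in-order character matching within a preceding word window
best_long_form <- function(short, pre) {
  short <- trimws(short)
  schars <- strsplit(tolower(short), "", fixed = TRUE)[[1]]
  schars <- schars[grepl("[[:alnum:]]", schars)]
  if (!length(schars)) return(NULL)
  # candidate window: last min(|A|+5, 2|A|) words before the parenthesis
  wm <- gregexpr("[^[:space:]]+", pre)[[1]]
  if (wm[1] == -1L) return(NULL)
  n_words <- min(length(schars) + 5L, 2L * length(schars))
  first_word <- max(1L, length(wm) - n_words + 1L)
  win_start <- as.integer(wm[first_word])
  window <- substring(pre, win_start, nchar(pre))
  lchars <- strsplit(tolower(window), "", fixed = TRUE)[[1]]

  li <- length(lchars)
  for (si in rev(seq_along(schars))) {
    c <- schars[si]
    repeat {
      if (li < 1L) return(NULL)
      ok <- lchars[li] == c
      if (ok && si == 1L && li > 1L && grepl("[[:alnum:]]", lchars[li - 1L]))
        ok <- FALSE  # first short-form char must start a word
      if (ok) break
      li <- li - 1L
    }
    first_match <- li
    li <- li - 1L
  }
  end_raw <- win_start + length(lchars) - 1L
  start_raw <- win_start + first_match - 1L
  text <- trimws(substring(pre, start_raw, end_raw))
  if (!nzchar(text)) return(NULL)
  list(text = text, start = start_raw,
       end = start_raw + nchar(text) - 1L)
}

#' The keyword list marking standard-outcome definitions
#'
#' The eleven words whose whole-word presence in an abbreviation definition
#' marks it as a candidate standard outcome measure.
#' @return Character vector of 11 keywords.
#' @export
standard_outcome_keywords <- function() {
  c("scale", "index", "score", "test", "questionnaire", "value", "count",
    "inventory", "assessment", "level", "rate")
}

#' Is a definition a standard-outcome candidate?
#'
#' `TRUE` iff any keyword occurs as a whole word (case-insensitive; any
#' non-alphanumeric character is a boundary, so "level-dependent" contains
#' "level").
#'
#' @param definition Character vector of candidate definitions.
#' @param keywords Keyword list; default [standard_outcome_keywords()].
#' @return Logical vector.
#' @examples
#' is_standard_candidate("Visual Analogue Scale")  # TRUE
#' is_standard_candidate("Body Mass")              # FALSE
#' @export
is_standard_candidate <- function(definition,
                                  keywords = standard_outcome_keywords()) {
  rx <- paste0("(?<![[:alnum:]])(", paste(keywords, collapse = "|"),
               ")(?![[:alnum:]])")
  grepl(rx, definition, perl = TRUE, ignore.case = TRUE)
}

#' Build the standard-outcome node set from outcome rows
#'
#' Mines abbreviation definitions from outcome titles and descriptions
#' ([find_abbreviations()]), keeps those containing a standard-outcome
#' keyword, folds variants via an override map, unions manual additions
#' (popular measures with no abbreviation, e.g. "Overall Survival"), and
#' deduplicates case-insensitively.
#'
#' @param outcomes A data.frame with columns `id`, `title`, `description`.
#' @param keywords Keyword filter list; default
#'   [standard_outcome_keywords()].
#' @param manual_additions Character vector of extra standard measures.
#' @param variant_overrides Named character vector (names = mined variant,
#'   values = canonical standard name).
#' @return A data.table of `StandardOutcome` nodes: `node_id`, `term`.
#' @export
build_standard_outcomes <- function(outcomes,
                                    keywords = standard_outcome_keywords(),
                                    manual_additions = character(0),
                                    variant_overrides = NULL) {
  oc <- data.table::as.data.table(outcomes)
  defs <- character(0)
  for (field in intersect(c("title", "description"), names(oc))) {
    for (txt in oc[[field]]) {
      if (is.na(txt) || !nzchar(txt)) next
      ab <- find_abbreviations(txt)
      if (nrow(ab)) defs <- c(defs, ab$definition)
    }
  }
  defs <- defs[is_standard_candidate(defs, keywords)]
  if (!is.null(variant_overrides)) {
    i <- match(tolower(trimws(defs)), tolower(trimws(names(variant_overrides))))
    defs[!is.na(i)] <- unname(variant_overrides[i[!is.na(i)]])
  }
  terms <- c(defs, as.character(manual_additions))
  terms <- terms[nzchar(trimws(terms))]
  terms <- terms[!duplicated(tolower(trimws(terms)))]
  terms <- terms[order(tolower(terms))]
  data.table::data.table(node_id = paste0("standardoutcome:", tolower(terms)),
                         term = terms)
}

#' Link outcomes to the standard measures their text contains
#'
#' An outcome links to a standard measure iff the standard's term occurs
#' case-insensitively as a substring of the outcome title or description; one
#' outcome may link to several standards ("... Platelet Count and White
#' Blood Cell Count" links to both counts).
#'
#' @param outcomes A data.frame with columns `id`, `title`, `description`.
#' @param standards A data.table from [build_standard_outcomes()].
#' @return A data.table of edges: `head_id` (outcome node id), `tail_id`
#'   (standard-outcome node id).
#' @export
link_standard_outcomes <- function(outcomes, standards) {
  oc <- data.table::as.data.table(outcomes)
  edges <- list()
  if (nrow(oc) && nrow(standards)) {
    txt <- tolower(paste(
      ifelse(is.na(oc$title), "", oc$title),
      if ("description" %in% names(oc))
        ifelse(is.na(oc$description), "", oc$description) else "",
      sep = " \n "))
    for (j in seq_len(nrow(standards))) {
      hit <- grepl(tolower(standards$term[j]), txt, fixed = TRUE)
      if (any(hit))
        edges[[length(edges) + 1L]] <- data.table::data.table(
          head_id = paste0("outcome:", oc$id[hit]),
          tail_id = standards$node_id[j])
    }
  }
  if (!length(edges))
    return(data.table::data.table(head_id = character(0),
                                  tail_id = character(0)))
  out <- data.table::rbindlist(edges)
  data.table::setorder(out, head_id, tail_id)
  out
}
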