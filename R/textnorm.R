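#' Levenshtein edit distance
#'
#' Unit-cost insertion/deletion/substitution distance between two strings (no
#' transposition), the string metric used throughout the normalizers: adverse
#' event terms are rescued to their nearest dictionary term when the distance
#' is at most 3, and squashed statistical-method names are merged under the
#' same threshold.
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of distances.
#' @examples
#' edit_distance("Cholecyctitis", "Cholecystitis")  # 1
#' edit_distance("kitten", "sitting")               # 3
#' @export
edit_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  d <- integer(n)
  for (i in seq_len(n)) d[i] <- as.integer(utils::adist(a[i], b[i])[1, 1])
  d
}

# distances from one string to many candidates (single adist call)
edit_distance_to <- function(x, candidates) {
  if (!length(candidates)) return(integer(0))
  as.integer(utils::adist(x, candidates)[1, ])
}

#' Remove balanced parenthesized content from text
#'
#' Deletes every outermost balanced `(...)` span (nested parentheses go with
#' their enclosing span) and collapses the surrounding whitespace. Unbalanced
#' parentheses are left untouched. Parenthesized content in event and outcome
#' titles is typically an explanation or afterthought ("Altered pitch
#' perception (pitch seemed lower)"), so dropping it preserves the main sense.
#'
#' @param t Character vector.
#' @return Character vector with balanced parenthetical spans removed.
#' @examples
#' strip_parenthetical("Altered pitch perception (pitch seemed lower)")
#' strip_parenthetical("a (b (c) d) e")  # "a e"
#' @export
strip_parenthetical <- function(t) {
  vapply(as.character(t), strip_parenthetical1, character(1), USE.NAMES = FALSE)
}

strip_parenthetical1 <- function(s) {
  if (is.na(s)) return(NA_character_)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  keep <- rep(TRUE, length(chars))
  stack <- integer(0)
  spans <- list()
  for (i in seq_along(chars)) {
    if (chars[i] == "(") stack <- c(stack, i)
    else if (chars[i] == ")" && length(stack)) {
      start <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!length(stack)) spans[[length(spans) + 1L]] <- c(start, i)
    }
  }
  for (sp in spans) keep[sp[1]:sp[2]] <- FALSE
  squeeze_ws(paste(chars[keep], collapse = ""))
}

#' Auxiliary-phrase pattern lists
#'
#' An ordered list of literal phrases and simple wildcard patterns describing
#' study-specific auxiliary information that appears inside adverse-event
#' terms but never inside dictionary terms: laterality and phase markers
#' ("left", "right", "Baseline Phase") and time frames ("for 12 hours"). Two
#' placeholder tokens are supported in patterns: `<number>` matches an integer
#' or decimal, `<time-unit>` matches second/minute/hour/day/week/month/year
#' with an optional plural "s". Matching is whole-token and, by default,
#' case-insensitive.
#'
#' `default_phrase_patterns()` loads the list shipped with the package;
#' `phrase_patterns()` builds one from character patterns or a resource file
#' (one pattern per line, `#` comments allowed).
#'
#' @param patterns Character vector of patterns.
#' @param file Path to a pattern file (used if `patterns` is missing).
#' @param ignore_case Match case-insensitively? Default `TRUE`.
#' @return An object of class `phrase_patterns`.
#' @export
phrase_patterns <- function(patterns = NULL, file = NULL, ignore_case = TRUE) {
  if (is.null(patterns)) {
    stopifnot(!is.null(file))
    patterns <- read_resource_lines(file)
  }
  patterns <- patterns[nzchar(trimws(patterns))]
  if (!length(patterns)) stop("phrase pattern list is empty", call. = FALSE)
  structure(list(patterns = patterns, ignore_case = ignore_case,
                 regex = vapply(patterns, phrase_to_regex, character(1))),
            class = "phrase_patterns")
}

#' @rdname phrase_patterns
#' @export
default_phrase_patterns <- function() {
  phrase_patterns(file = system.file("extdata", "aux_phrases.txt",
                                     package = "trialgraph", mustWork = TRUE))
}

# literal phrase (with placeholder tokens) -> whole-token regex
phrase_to_regex <- function(p) {
  toks <- strsplit(trimws(p), "[[:space:]]+")[[1]]
  rx <- vapply(toks, function(tok) {
    if (tok == "<number>") "[0-9]+(?:\\.[0-9]+)?"
    else if (tok == "<time-unit>")
      "(?:second|minute|hour|day|week|month|year)s?"
    else gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", tok, perl = TRUE)
  }, character(1))
  paste0("(?<![[:alnum:]])", paste(rx, collapse = "[[:space:]]+"),
         "(?![[:alnum:]])")
}

#' Remove auxiliary phrases from a term
#'
#' Deletes every whole-token occurrence of the listed phrases, then cleans up
#' dangling separators ("-", ",") and duplicate spaces left behind. Applied as
#' the phrase-removal stage of the adverse-event normalization cascade: "Throat
#' tightness - Baseline Phase" becomes "Throat tightness".
#'
#' @param t Character vector.
#' @param pats A `phrase_patterns` object; default
#'   [default_phrase_patterns()].
#' @return Character vector with the phrases removed.
#' @export
remove_phrases <- function(t, pats = default_phrase_patterns()) {
  stopifnot(inherits(pats, "phrase_patterns"))
  out <- as.character(t)
  # mark removed spans so separators they leave dangling can be cleaned
  for (rx in pats$regex)
    out <- gsub(rx, "\u0001", out, perl = TRUE, ignore.case = pats$ignore_case)
  out <- gsub("[[:space:]]*[-,]?[[:space:]]*\u0001+[[:space:]]*[-,]?[[:space:]]*",
              " ", out)
  out <- gsub("^[-,[:space:]]+|[-,[:space:]]+$", "", out)
  squeeze_ws(out)
}

#' Lowercase, remove stop words and lemmatize
#'
#' Tokenizes on whitespace, lowercases, drops stop words, lemmatizes each
#' remaining token (exception-table lookup first, then a conservative plural
#' rule), and rejoins with single spaces. Deterministic for a fixed stop-word
#' list and lemma table; both are plain-text resources shipped with the
#' package and can be overridden.
#'
#' @param t Character vector.
#' @param stopwords Character vector of stop words; default the shipped list.
#' @param lemmas Named character vector mapping inflected form to lemma;
#'   default the shipped table.
#' @return Character vector of simplified terms.
#' @examples
#' simplify_tokens("Pain in the arms")  # "pain arm"
#' @export
simplify_tokens <- function(t, stopwords = default_stopwords(),
                            lemmas = default_lemmas()) {
  vapply(as.character(t), function(s) {
    if (is.na(s)) return(NA_character_)
    toks <- strsplit(tolower(squeeze_ws(s)), " ", fixed = TRUE)[[1]]
    toks <- toks[!toks %in% stopwords]
    toks <- vapply(toks, function(w) {
      if (!is.na(lemmas[w])) return(unname(lemmas[w]))
      lemmatize_plural(w)
    }, character(1))
    paste(toks, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# conservative rule-based singularization for out-of-table tokens
lemmatize_plural <- function(w) {
  if (nchar(w) <= 3L) return(w)
  if (grepl("ies$", w)) return(sub("ies$", "y", w))
  if (grepl("(ss|us|is)$", w)) return(w)
  if (grepl("(ch|sh|x|z|s)es$", w)) return(sub("es$", "", w))
  if (grepl("s$", w)) return(sub("s$", "", w))
  w
}

#' @rdname simplify_tokens
#' @export
default_stopwords <- function() {
  read_resource_lines(system.file("extdata", "stopwords.txt",
                                  package = "trialgraph", mustWork = TRUE))
}

#' @rdname simplify_tokens
#' @export
default_lemmas <- function() {
  f <- system.file("extdata", "lemmas.tsv", package = "trialgraph",
                   mustWork = TRUE)
  tab <- data.table::fread(f, sep = "\t", header = TRUE,
                           colClasses = "character")
  stats::setNames(tab$lemma, tab$form)
}

#' Squash a name to lowercase alphanumerics
#'
#' Lowercases and removes all whitespace and punctuation, the preprocessing
#' applied to statistical-method names before edit-distance comparison:
#' "paired t test", "paired t-test" and "Paired T-Tests" squash to
#' "pairedttest"/"pairedttests".
#'
#' @param t Character vector.
#' @return Character vector containing only lowercase alphanumerics.
#' @export
squash <- function(t) {
  gsub("[^[:alnum:]]+", "", tolower(as.character(t)))
}

read_resource_lines <- function(file) {
  x <- readLines(file, encoding = "UTF-8", warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
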