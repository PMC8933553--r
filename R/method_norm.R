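#' Canonicalize statistical-analysis method names
#'
#' Three-step normalization of the method names attached to outcome analyses:
#' \enumerate{
#'   \item each name is squashed to lowercase alphanumerics ([squash()]), so
#'     "paired t test", "paired t-tests" and "paited t-test" become
#'     comparable;
#'   \item names whose squashed forms fall in the same single-linkage
#'     connected component under Levenshtein distance at most 3 share one
#'     canonical name — the member raw name with the highest total occurrence
#'     count, ties broken lexicographically;
#'   \item components whose canonical names contain the same words in any
#'     order (equal token multisets after case-folding and punctuation
#'     splitting, e.g. "paired t-test" vs "t-test, paired") are merged, again
#'     keeping the highest-count canonical.
#' }
#' Single linkage is the minimal closure of the pairwise merge rule: a chain
#' a-b-c where only adjacent pairs are within distance 3 still collapses to
#' one canonical. An optional override map (raw name to forced canonical),
#' applied last, reproduces a manual correction pass.
#'
#' @param counts Named integer vector (names = raw method names, values =
#'   occurrence counts >= 1), or a two-column data.frame (`name`, `count`).
#' @param overrides Optional named character vector (names = raw names,
#'   values = forced canonical names).
#' @return Named character vector mapping every raw name to its canonical
#'   name; total and invariant to input order.
#' @examples
#' canonicalize_methods(c("paired t test" = 5, "paired t-tests" = 2,
#'                        "paited t-test" = 1))
#' @export
canonicalize_methods <- function(counts, overrides = NULL) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("name", "count") %in% names(counts)))
    counts <- stats::setNames(as.integer(counts$count),
                              as.character(counts$name))
  }
  if (!length(counts)) stop("method name table is empty", call. = FALSE)
  if (any(is.na(counts) | counts < 1L))
    stop("method counts must be positive", call. = FALSE)
  # deterministic regardless of input row order
  counts <- counts[order(names(counts))]
  nm <- names(counts)
  n <- length(nm)
  sq <- squash(nm)

  # single-linkage components over squashed forms, distance <= 3
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[min(ri, rj)] <<- min(ri, rj)  # keep smallest root
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  if (n > 1L) {
    len <- nchar(sq)
    d <- utils::adist(sq, sq)
    for (i in seq_len(n - 1L)) for (j in seq((i + 1L), n)) {
      if (abs(len[i] - len[j]) > 3L) next
      if (identical(sq[i], sq[j]) || d[i, j] <= 3L) union_(i, j)
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))

  pick_canonical <- function(members) {
    cnt <- counts[members]
    members[order(-cnt, names(cnt))][1]
  }
  comp_ids <- unique(comp)
  canon <- vapply(comp_ids, function(cid)
    pick_canonical(nm[comp == cid]), character(1))
  names(canon) <- as.character(comp_ids)

  # step 3: merge components whose canonical names share a token multiset
  token_key <- function(x) {
    toks <- strsplit(tolower(x), "[^[:alnum:]]+")[[1]]
    toks <- sort(toks[nzchar(toks)])
    paste(toks, collapse = " ")
  }
  keys <- vapply(canon, token_key, character(1))
  merged_canon <- canon
  for (k in unique(keys)) {
    grp <- names(canon)[keys == k]
    if (length(grp) > 1L) {
      members <- nm[comp %in% as.integer(grp)]
      merged_canon[grp] <- pick_canonical(members)
    }
  }

  out <- merged_canon[as.character(comp)]
  names(out) <- nm
  if (!is.null(overrides)) {
    i <- match(tolower(trimws(nm)), tolower(trimws(names(overrides))))
    out[!is.na(i)] <- unname(overrides[i[!is.na(i)]])
  }
  out
}
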