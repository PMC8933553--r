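# Independent oracles used across the suite.

# top-down recursive Levenshtein with per-pair memoization; independent of
# the implementation under test
oracle_levenshtein <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1]]
  bv <- strsplit(b, "", fixed = TRUE)[[1]]
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (i == 0L) return(j)
    if (j == 0L) return(i)
    k <- paste0(i, ",", j)
    if (!is.null(memo[[k]])) return(memo[[k]])
    cost <- if (av[i] == bv[j]) 0L else 1L
    v <- min(rec(i - 1L, j) + 1L, rec(i, j - 1L) + 1L,
             rec(i - 1L, j - 1L) + cost)
    memo[[k]] <- v
    v
  }
  rec(length(av), length(bv))
}

# every string over `alphabet` of length <= n
all_strings_upto <- function(n, alphabet = c("a", "b", "c")) {
  out <- ""
  for (len in seq_len(n)) {
    grid <- do.call(expand.grid,
                    c(rep(list(alphabet), len), stringsAsFactors = FALSE))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# the Schwartz-Hearst output invariant: every abbreviation character occurs,
# in order and case-insensitively, in the definition, with the first matched
# character starting a word; the definition precedes the abbreviation
abbrev_pair_valid <- function(pair, text) {
  ab <- tolower(pair$abbreviation)
  def <- tolower(pair$definition)
  achars <- strsplit(ab, "", fixed = TRUE)[[1]]
  achars <- achars[grepl("[[:alnum:]]", achars)]
  dchars <- strsplit(def, "", fixed = TRUE)[[1]]
  pos <- 0L
  first_pos <- NA_integer_
  for (k in seq_along(achars)) {
    hit <- which(dchars[seq.int(pos + 1L, length(dchars))] == achars[k])
    if (!length(hit)) return(FALSE)
    pos <- pos + hit[1]
    if (k == 1L) first_pos <- pos
  }
  word_initial <- first_pos == 1L ||
    !grepl("[[:alnum:]]", dchars[first_pos - 1L])
  precedes <- pair$long_end < pair$short_start
  word_initial && precedes
}

# do two cluster assignments define the same partition?
same_partition <- function(a, b) {
  identical(
    unname(split(seq_along(a), a)[order(vapply(split(seq_along(a), a),
                                               min, integer(1)))]),
    unname(split(seq_along(b), b)[order(vapply(split(seq_along(b), b),
                                               min, integer(1)))]))
}

# brute-force all-pairs single-linkage components via union-find, for the
# method-name merge rule (distance <= 3 on squashed forms)
oracle_components <- function(squashed) {
  n <- length(squashed)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    if (utils::adist(squashed[i], squashed[j]) <= 3) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}
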