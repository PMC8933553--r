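#' TF-IDF vectors for short texts
#'
#' Tokenizes on non-alphanumeric characters, lowercases, removes stop words,
#' weights term counts by smoothed inverse document frequency
#' `log((1 + N) / (1 + df)) + 1`, and L2-normalizes each row. Documents with
#' no surviving token become zero rows.
#'
#' @param texts Character vector of documents.
#' @param stopwords Stop-word list; default [default_stopwords()].
#' @return A dense numeric matrix (documents x vocabulary) with unit-norm
#'   rows, column names = vocabulary.
#' @export
tfidf_matrix <- function(texts, stopwords = default_stopwords()) {
  toks <- lapply(texts, function(s) {
    if (is.na(s)) return(character(0))
    w <- strsplit(tolower(s), "[^[:alnum:]]+")[[1]]
    w[nzchar(w) & !w %in% stopwords]
  })
  vocab <- sort(unique(unlist(toks)))
  n <- length(texts)
  X <- matrix(0, nrow = n, ncol = length(vocab),
              dimnames = list(NULL, vocab))
  for (i in seq_len(n)) {
    if (!length(toks[[i]])) next
    tab <- table(toks[[i]])
    X[i, names(tab)] <- as.numeric(tab)
  }
  if (length(vocab)) {
    df <- colSums(X > 0)
    idf <- log((1 + n) / (1 + df)) + 1
    X <- sweep(X, 2, idf, `*`)
    nrm <- sqrt(rowSums(X^2))
    nz <- nrm > 0
    X[nz, ] <- X[nz, , drop = FALSE] / nrm[nz]
  }
  X
}

#' Cluster outcome titles by repeated-bisection spherical clustering
#'
#' Represents each title as a unit-norm TF-IDF vector and partitions the
#' titles into `k` clusters by repeated bisection: starting from one cluster,
#' the largest cluster is repeatedly split by spherical 2-means (several
#' seeded restarts, assignment by cosine), keeping the bisection that
#' maximizes the clustering criterion — the sum over clusters of the norm of
#' the cluster composite (sum) vector.
#'
#' Each cluster is summarized by its 5 most descriptive and 5 most
#' discriminating words: the descriptive percentage of word `w` is its share
#' of the squared cluster centroid, `100 * c_w^2 / sum(c^2)`; the
#' discriminating percentage is its share of the squared difference between
#' the cluster centroid and the centroid of the complement,
#' `100 * (c_w - o_w)^2 / sum((c - o)^2)`. For `k = 1` the two summaries
#' coincide.
#'
#' @param titles Character vector of outcome titles.
#' @param k Number of clusters, `1 <= k <= length(titles)`.
#' @param seed Integer seed fixing all restarts; the result is reproducible.
#' @param ids Optional ids naming the assignment; default the title index.
#' @return An object of class `outcome_cluster_report`: list with `k`,
#'   `assignment` (named integer vector of cluster ids 1..k), `sizes`, and
#'   per-cluster `descriptive` / `discriminating` data.tables
#'   (`word`, `pct`, non-increasing).
#' @export
cluster_outcomes <- function(titles, k, seed = 1L, ids = NULL) {
  n <- length(titles)
  if (k < 1L) stop("k must be at least 1", call. = FALSE)
  if (k > n) stop("k exceeds the number of titles", call. = FALSE)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  X <- tfidf_matrix(titles)
  assign_vec <- with_seed(seed, repeated_bisection(X, k))

  centroid <- function(members)
    if (length(members)) colMeans(X[members, , drop = FALSE])
    else rep(0, ncol(X))
  descriptive <- vector("list", k)
  discriminating <- vector("list", k)
  for (c_id in seq_len(k)) {
    inside <- which(assign_vec == c_id)
    cv <- centroid(inside)
    dsc <- summarize_weights(cv^2)
    comp <- setdiff(seq_len(n), inside)
    dv <- if (length(comp)) (cv - centroid(comp))^2 else cv^2
    descriptive[[c_id]] <- dsc
    discriminating[[c_id]] <- summarize_weights(dv)
  }
  names(assign_vec) <- ids
  structure(list(k = k, assignment = assign_vec,
                 sizes = as.integer(table(factor(assign_vec, 1:k))),
                 descriptive = descriptive,
                 discriminating = discriminating),
            class = "outcome_cluster_report")
}

# top-5 (word, pct) pairs from a vector of non-negative weights
summarize_weights <- function(w) {
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0)
    return(data.table::data.table(word = character(0), pct = numeric(0)))
  pct <- 100 * w / tot
  ord <- order(-pct, names(pct))
  top <- ord[pct[ord] > 0][seq_len(min(5L, sum(pct > 0)))]
  data.table::data.table(word = names(pct)[top], pct = unname(pct[top]))
}

repeated_bisection <- function(X, k) {
  n <- nrow(X)
  assign_vec <- rep(1L, n)
  if (k == 1L) return(assign_vec)
  for (next_id in 2:k) {
    sizes <- tabulate(assign_vec, nbins = next_id - 1L)
    splittable <- which(sizes > 1L)
    if (!length(splittable)) break
    target <- splittable[which.max(sizes[splittable])]
    members <- which(assign_vec == target)
    halves <- bisect_spherical(X[members, , drop = FALSE])
    assign_vec[members[halves == 2L]] <- next_id
  }
  assign_vec
}

# spherical 2-means with restarts; returns 1/2 labels, both halves non-empty
bisect_spherical <- function(Xs, restarts = 5L, iters = 25L) {
  m <- nrow(Xs)
  best <- NULL
  best_crit <- -Inf
  for (r in seq_len(restarts)) {
    seeds <- sample.int(m, 2L)
    cen <- Xs[seeds, , drop = FALSE]
    lab <- rep(1L, m)
    for (it in seq_len(iters)) {
      sim <- Xs %*% t(cen)
      new_lab <- max.col(sim, ties.method = "first")
      if (length(unique(new_lab)) == 1L) {
        # degenerate: peel off the point least similar to the centroid
        far <- which.min(sim[, new_lab[1]])
        new_lab[far] <- 3L - new_lab[1]
      }
      if (identical(new_lab, lab) && it > 1L) break
      lab <- new_lab
      for (g in 1:2) {
        v <- colSums(Xs[lab == g, , drop = FALSE])
        nv <- sqrt(sum(v^2))
        cen[g, ] <- if (nv > 0) v / nv else 0
      }
    }
    crit <- composite_norm(Xs[lab == 1L, , drop = FALSE]) +
      composite_norm(Xs[lab == 2L, , drop = FALSE])
    if (crit > best_crit) { best_crit <- crit; best <- lab }
  }
  best
}

composite_norm <- function(Xs) {
  if (!nrow(Xs)) return(0)
  sqrt(sum(colSums(Xs)^2))
}

#' Tabular form of a cluster report
#'
#' One row per cluster with the size and the "word pct%" comma-joined
#' descriptive and discriminating summaries, the format used for
#' cluster-outcome node attributes (e.g. "circumference 56.4%, waist 43.0%").
#'
#' @param report An `outcome_cluster_report`.
#' @return A data.table with columns `cluster_id`, `size`, `descriptive`,
#'   `discriminating`.
#' @export
cluster_report_table <- function(report) {
  stopifnot(inherits(report, "outcome_cluster_report"))
  fmt <- function(tab)
    paste(sprintf("%s %.1f%%", tab$word, tab$pct), collapse = ", ")
  data.table::data.table(
    cluster_id = seq_len(report$k),
    size = report$sizes,
    descriptive = vapply(report$descriptive, fmt, character(1)),
    discriminating = vapply(report$discriminating, fmt, character(1)))
}

#' @export
print.outcome_cluster_report <- function(x, ...) {
  cat(sprintf("<outcome_cluster_report> k = %d over %d titles\n",
              x$k, length(x$assignment)))
  invisible(x)
}
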