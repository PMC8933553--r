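#' Training configuration for translational embeddings
#'
#' Hyperparameters of the TransE trainer. Defaults are the library-default
#' desk scale: 200 dimensions, margin 1, L2 distance, learning rate 0.01,
#' 200 epochs, one uniformly sampled corruption per positive. The seed fixes
#' initialization, shuffling and negative sampling, making training
#' bit-reproducible.
#'
#' @param dim Embedding dimension (positive integer).
#' @param margin Margin of the ranking loss (positive).
#' @param norm_order 1 or 2; the distance norm.
#' @param learning_rate SGD step size (positive).
#' @param epochs Number of passes over the edge set.
#' @param negatives_per_positive Corruptions sampled per positive triple.
#' @param batch_size Mini-batch size.
#' @param seed Integer seed.
#' @return A list of class `train_config`.
#' @export
train_config <- function(dim = 200L, margin = 1, norm_order = 2L,
                         learning_rate = 0.01, epochs = 200L,
                         negatives_per_positive = 1L, batch_size = 512L,
                         seed = 1L) {
  stopifnot(dim >= 1, margin > 0, norm_order %in% c(1L, 2L),
            learning_rate > 0, epochs >= 1, negatives_per_positive >= 1,
            batch_size >= 1)
  structure(list(dim = as.integer(dim), margin = margin,
                 norm_order = as.integer(norm_order),
                 learning_rate = learning_rate, epochs = as.integer(epochs),
                 negatives_per_positive = as.integer(negatives_per_positive),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "train_config")
}

kg_triples <- function(kg) {
  data.table::rbindlist(lapply(names(kg$edges), function(r) {
    ed <- kg$edges[[r]]
    if (!nrow(ed)) return(NULL)
    data.table::data.table(head_id = ed$head_id, relation = r,
                           tail_id = ed$tail_id)
  }))
}

#' Train TransE embeddings on a knowledge graph
#'
#' Learns one real vector per node and per relation type such that for an
#' observed triple (h, r, t) the translation `v_h + v_r` lies close to `v_t`.
#' Training minimizes the margin ranking loss
#' `sum(max(0, margin + d(h,r,t) - d(h',r,t')))` over observed triples
#' against corrupted ones by mini-batch SGD, where each corruption replaces
#' the head or the tail (equal probability) with a node drawn uniformly from
#' the nodes of the type the relation's schema permits in that slot — a
#' type-respecting variant of uniform negative sampling. Node attributes are
#' not used: embeddings reflect graph topology only. Entity vectors are
#' renormalized to unit norm after every epoch.
#'
#' @param kg A `trial_kg` with at least one edge.
#' @param config A [train_config()].
#' @return An object of class `embedding_table`: list with `entities`
#'   (matrix, rownames = node ids), `relations` (matrix, rownames = relation
#'   names), `loss` (mean epoch loss trajectory) and `config`.
#' @export
train_transe <- function(kg, config = train_config()) {
  stopifnot(inherits(kg, "trial_kg"), inherits(config, "train_config"))
  tr <- kg_triples(kg)
  if (is.null(tr) || !nrow(tr)) stop("graph has no edges", call. = FALSE)

  idx <- kg_node_index(kg)
  ents <- idx$node_id
  ent_type <- idx$node_type
  rels <- kg$schema$relations$relation
  type_pool <- split(seq_along(ents), ent_type)

  h <- match(tr$head_id, ents)
  t <- match(tr$tail_id, ents)
  r <- match(tr$relation, rels)
  head_type <- kg$schema$relations$head_type[r]
  tail_type <- kg$schema$relations$tail_type[r]

  n_ent <- length(ents)
  n_tr <- length(h)
  dim <- config$dim
  lr <- config$learning_rate
  margin <- config$margin
  p <- config$norm_order

  with_seed(config$seed, {
    bound <- 6 / sqrt(dim)
    E <- matrix(stats::runif(n_ent * dim, -bound, bound), n_ent, dim)
    E <- E / sqrt(rowSums(E^2))
    R <- matrix(stats::runif(length(rels) * dim, -bound, bound),
                length(rels), dim)
    R <- R / sqrt(rowSums(R^2))
    loss_trace <- numeric(config$epochs)

    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n_tr)
      total <- 0
      n_terms <- 0L
      for (start in seq(1L, n_tr, by = config$batch_size)) {
        b <- ord[start:min(start + config$batch_size - 1L, n_tr)]
        nb <- length(b)
        for (neg in seq_len(config$negatives_per_positive)) {
          hb <- h[b]; tb <- t[b]; rb <- r[b]
          corrupt_head <- stats::runif(nb) < 0.5
          hn <- hb; tn <- tb
          for (i in seq_len(nb)) {
            pool <- type_pool[[if (corrupt_head[i]) head_type[b[i]]
                               else tail_type[b[i]]]]
            pick <- pool[sample.int(length(pool), 1L)]
            if (corrupt_head[i]) hn[i] <- pick else tn[i] <- pick
          }
          dp_vec <- E[hb, , drop = FALSE] + R[rb, , drop = FALSE] -
            E[tb, , drop = FALSE]
          dn_vec <- E[hn, , drop = FALSE] + R[rb, , drop = FALSE] -
            E[tn, , drop = FALSE]
          if (p == 2L) {
            dp <- sqrt(rowSums(dp_vec^2)); dn <- sqrt(rowSums(dn_vec^2))
            gp <- dp_vec / pmax(dp, 1e-12)
            gn <- dn_vec / pmax(dn, 1e-12)
          } else {
            dp <- rowSums(abs(dp_vec)); dn <- rowSums(abs(dn_vec))
            gp <- sign(dp_vec); gn <- sign(dn_vec)
          }
          viol <- margin + dp - dn > 0
          total <- total + sum(pmax(0, margin + dp - dn))
          n_terms <- n_terms + nb
          if (!any(viol)) next
          gp <- gp[viol, , drop = FALSE]
          gn <- gn[viol, , drop = FALSE]
          upd <- function(M, ix, G) {
            S <- rowsum(G, group = ix)
            u <- as.integer(rownames(S))
            M[u, ] <- M[u, ] - lr * S
            M
          }
          E <- upd(E, hb[viol], gp)
          E <- upd(E, tb[viol], -gp)
          R <- upd(R, rb[viol], gp)
          E <- upd(E, hn[viol], -gn)
          E <- upd(E, tn[viol], gn)
          R <- upd(R, rb[viol], -gn)
        }
      }
      E <- E / sqrt(rowSums(E^2))
      loss_trace[epoch] <- total / n_terms
    }
    rownames(E) <- ents
    rownames(R) <- rels
    structure(list(entities = E, relations = R, loss = loss_trace,
                   config = config),
              class = "embedding_table")
  })
}

#' @export
print.embedding_table <- function(x, ...) {
  cat(sprintf("<embedding_table> %d entities, %d relations, dim %d, final loss %.4f\n",
              nrow(x$entities), nrow(x$relations), ncol(x$entities),
              utils::tail(x$loss, 1)))
  invisible(x)
}

#' Plausibility score of a triple under a TransE embedding
#'
#' Returns `-||v_h + v_r - v_t||` under the configured norm; higher scores
#' mean more plausible triples, with 0 the maximum (exact translation).
#'
#' @param emb An `embedding_table`.
#' @param h,t Node ids (vectors of equal length are scored element-wise).
#' @param r Relation type name(s).
#' @return Numeric vector of scores.
#' @export
score_triple <- function(emb, h, r, t) {
  stopifnot(inherits(emb, "embedding_table"))
  bad <- setdiff(c(h, t), rownames(emb$entities))
  if (length(bad)) stop("unknown node id(s): ",
                        paste(utils::head(bad, 3), collapse = ", "),
                        call. = FALSE)
  if (!all(r %in% rownames(emb$relations)))
    stop("unknown relation", call. = FALSE)
  v <- emb$entities[h, , drop = FALSE] + emb$relations[r, , drop = FALSE] -
    emb$entities[t, , drop = FALSE]
  unname(if (emb$config$norm_order == 2L) -sqrt(rowSums(v^2))
         else -rowSums(abs(v)))
}

cosine_rows <- function(M) {
  nrm <- sqrt(rowSums(M^2))
  M / pmax(nrm, 1e-12)
}

#' Most similar node pairs between two node types
#'
#' Computes exact cosine similarities between the embeddings of all nodes of
#' two types and returns the top-k pairs (ties broken by node ids), together
#' with the mean pairwise similarity between the types — the baseline against
#' which high similarities are judged. For a single type, self-pairs are
#' excluded and unordered pairs are reported once.
#'
#' @param emb An `embedding_table`.
#' @param kg The `trial_kg` the embedding was trained on (supplies node
#'   types).
#' @param type_a,type_b Node type names (may be equal).
#' @param k Number of pairs (positive).
#' @return A list: `pairs` (data.table `id_a`, `id_b`, `cosine`, decreasing)
#'   and `mean_similarity`.
#' @export
topk_similar <- function(emb, kg, type_a, type_b, k = 10L) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  ids_a <- intersect(kg$nodes[[type_a]]$node_id, rownames(emb$entities))
  ids_b <- intersect(kg$nodes[[type_b]]$node_id, rownames(emb$entities))
  if (!length(ids_a) || !length(ids_b))
    stop("no embedded nodes of the requested type(s)", call. = FALSE)
  A <- cosine_rows(emb$entities[ids_a, , drop = FALSE])
  B <- cosine_rows(emb$entities[ids_b, , drop = FALSE])
  S <- A %*% t(B)
  same <- identical(type_a, type_b)
  dt <- data.table::data.table(
    id_a = rep(ids_a, times = length(ids_b)),
    id_b = rep(ids_b, each = length(ids_a)),
    cosine = as.vector(S))
  if (same) dt <- dt[id_a < id_b]
  mean_sim <- mean(dt$cosine)
  data.table::setorder(dt, -cosine, id_a, id_b)
  list(pairs = dt[seq_len(min(k, nrow(dt)))], mean_similarity = mean_sim)
}

# condition-drug pairs connected through a shared study
co_studied_pairs <- function(kg) {
  sc <- kg$edges[["Study-Condition"]]
  sd <- data.table::rbindlist(list(kg$edges[["Study-StudiedDrug"]],
                                   kg$edges[["Study-UsedDrug"]]))
  if (!nrow(sc) || !nrow(sd))
    return(data.table::data.table(condition = character(0),
                                  drug = character(0)))
  m <- merge(sc[, list(study = head_id, condition = tail_id)],
             sd[, list(study = head_id, drug = tail_id)],
             by = "study", allow.cartesian = TRUE)
  unique(m[, list(condition, drug)])
}

#' Rank condition-drug repurposing candidates
#'
#' Ranks condition/drug-term pairs by embedding cosine similarity after
#' excluding every pair already connected through a shared study (the
#' condition and the drug both linked to the same study node): a drug highly
#' similar to a condition it was never studied for is a repurposing
#' candidate.
#'
#' @param emb An `embedding_table`.
#' @param kg The `trial_kg` the embedding was trained on.
#' @param k Number of candidate pairs.
#' @return A data.table `condition`, `drug`, `cosine`, decreasing; the
#'   attribute `"mean_similarity"` carries the all-pairs baseline.
#' @export
repurposing_candidates <- function(emb, kg, k = 10L) {
  all_pairs <- topk_similar(emb, kg, "Condition", "DrugTerm",
                            k = .Machine$integer.max)
  dt <- data.table::setnames(all_pairs$pairs,
                             c("id_a", "id_b"), c("condition", "drug"))
  excl <- co_studied_pairs(kg)
  if (nrow(excl)) dt <- dt[!excl, on = c("condition", "drug")]
  out <- dt[seq_len(min(k, nrow(dt)))]
  data.table::setattr(out, "mean_similarity", all_pairs$mean_similarity)
  out
}

#' Ranking quality of an embedding: hits at k against random corruptions
#'
#' Samples observed triples, corrupts the tail of each with `n_corruptions`
#' uniformly drawn nodes of the schema-permitted type, ranks the true tail
#' among the corruptions by [score_triple()], and reports the fraction of
#' true triples ranked within the top `k` (chance rate
#' `k / (n_corruptions + 1)` for an uninformative embedding).
#'
#' @param emb An `embedding_table`.
#' @param kg The graph supplying triples and type pools.
#' @param n_triples Number of triples sampled (capped at the edge count).
#' @param n_corruptions Corruptions per triple.
#' @param k Rank cutoff.
#' @param seed Integer seed for sampling.
#' @return The hits-at-k rate (numeric scalar in `[0, 1]`).
#' @export
embedding_hits_at_k <- function(emb, kg, n_triples = 200L,
                                n_corruptions = 50L, k = 10L, seed = 1L) {
  tr <- kg_triples(kg)
  idx <- kg_node_index(kg)
  pools <- split(idx$node_id, idx$node_type)
  tail_type <- stats::setNames(kg$schema$relations$tail_type,
                               kg$schema$relations$relation)
  with_seed(seed, {
    take <- sample.int(nrow(tr), min(n_triples, nrow(tr)))
    hits <- vapply(take, function(i) {
      pool <- pools[[tail_type[[tr$relation[i]]]]]
      corr <- pool[sample.int(length(pool), min(n_corruptions, length(pool)),
                              replace = length(pool) < n_corruptions)]
      s_true <- score_triple(emb, tr$head_id[i], tr$relation[i], tr$tail_id[i])
      s_corr <- score_triple(emb, rep(tr$head_id[i], length(corr)),
                             rep(tr$relation[i], length(corr)), corr)
      rank <- 1L + sum(s_corr > s_true)
      rank <= k
    }, logical(1))
    mean(hits)
  })
}
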