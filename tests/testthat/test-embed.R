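manual_embedding <- function(entities, relations, norm_order = 2L) {
  structure(list(entities = entities, relations = relations,
                 loss = NA_real_,
                 config = train_config(dim = ncol(entities),
                                       norm_order = norm_order)),
            class = "embedding_table")
}

test_that("triple scores are negative translation distances", {
  E <- rbind("a" = c(1, 0), "b" = c(1, 1), "c" = c(0, 0))
  R <- rbind("r" = c(0, 1))
  emb <- manual_embedding(E, R)
  # exact translation scores 0 (the maximum)
  expect_equal(score_triple(emb, "a", "r", "b"), 0)
  # hand arithmetic: -(norm of (1,0)+(0,1)-(0,0)) = -sqrt(2)
  expect_equal(score_triple(emb, "a", "r", "c"), -sqrt(2))
  emb1 <- manual_embedding(E, R, norm_order = 1L)
  expect_equal(score_triple(emb1, "a", "r", "c"), -2)
  expect_error(score_triple(emb, "ghost", "r", "b"), "unknown node")
  expect_error(score_triple(emb, "a", "ghost", "b"), "unknown relation")
})

test_that("L2 scores are invariant under joint orthogonal rotation", {
  set.seed(5)
  E <- matrix(rnorm(12), 4, 3, dimnames = list(letters[1:4], NULL))
  R <- matrix(rnorm(3), 1, 3, dimnames = list("r", NULL))
  Q <- qr.Q(qr(matrix(rnorm(9), 3, 3)))
  emb <- manual_embedding(E, R)
  emb_rot <- manual_embedding(E %*% Q, R %*% Q)
  for (h in letters[1:4]) for (t in letters[1:4])
    expect_equal(score_triple(emb, h, "r", t),
                 score_triple(emb_rot, h, "r", t))
})

fixture_kg <- function(seed = 3L, n_studies = 30L) {
  fx <- generate_fixture(fixture_config(n_studies = n_studies, seed = seed))
  assemble(fx$tables, fx$dict, fx$lexicon,
           assemble_config(clusters = 4L, seed = 2L))
}

test_that("training is deterministic and its loss trend decreases", {
  kg <- fixture_kg(seed = 3L, n_studies = 15L)
  cfg <- train_config(dim = 12L, epochs = 20L, seed = 7L, batch_size = 256L)
  e1 <- train_transe(kg, cfg)
  e2 <- train_transe(kg, cfg)
  expect_identical(e1$entities, e2$entities)
  expect_identical(e1$relations, e2$relations)
  # entity vectors are unit norm after the final epoch renormalization
  expect_equal(unname(sqrt(rowSums(e1$entities^2))),
               rep(1, nrow(e1$entities)))
  # moving-average loss is non-increasing from start to end
  ma <- stats::filter(e1$loss, rep(1 / 5, 5), sides = 1)
  ma <- ma[!is.na(ma)]
  expect_lt(ma[length(ma)], ma[1])
  expect_error(train_transe(kg_new(), cfg), "no edges")
})

test_that("top-k retrieval equals a brute-force all-pairs sort", {
  kg <- kg_new()
  kg <- kg_add_nodes(kg, "Condition", data.frame(
    node_id = paste0("condition:c", 1:3), term = paste0("c", 1:3)))
  kg <- kg_add_nodes(kg, "DrugTerm", data.frame(
    node_id = paste0("drugterm:d", 1:2), term = paste0("d", 1:2)))
  set.seed(11)
  E <- matrix(rnorm(5 * 4), 5, 4,
              dimnames = list(c(paste0("condition:c", 1:3),
                                paste0("drugterm:d", 1:2)), NULL))
  emb <- manual_embedding(E, matrix(0, 0, 4))
  res <- topk_similar(emb, kg, "Condition", "DrugTerm", k = 6L)
  # oracle: explicit double loop
  oracle <- data.frame()
  for (i in 1:3) for (j in 1:2) {
    a <- E[i, ]; b <- E[3 + j, ]
    oracle <- rbind(oracle, data.frame(
      id_a = rownames(E)[i], id_b = rownames(E)[3 + j],
      cosine = sum(a * b) / sqrt(sum(a^2) * sum(b^2))))
  }
  oracle <- oracle[order(-oracle$cosine, oracle$id_a, oracle$id_b), ]
  expect_equal(res$pairs$cosine, oracle$cosine)
  expect_identical(res$pairs$id_a, oracle$id_a)
  expect_identical(res$pairs$id_b, oracle$id_b)
  expect_equal(res$mean_similarity, mean(oracle$cosine))
  expect_error(topk_similar(emb, kg, "Condition", "DrugTerm", k = 0L),
               "positive")
})

test_that("identical and orthogonal vectors score 1 and 0", {
  kg <- kg_new()
  kg <- kg_add_nodes(kg, "Condition",
                     data.frame(node_id = "condition:a", term = "a"))
  kg <- kg_add_nodes(kg, "DrugTerm", data.frame(
    node_id = c("drugterm:same", "drugterm:orth"), term = c("s", "o")))
  E <- rbind("condition:a" = c(1, 0), "drugterm:same" = c(2, 0),
             "drugterm:orth" = c(0, 3))
  emb <- manual_embedding(E, matrix(0, 0, 2))
  res <- topk_similar(emb, kg, "Condition", "DrugTerm", k = 2L)
  expect_equal(res$pairs$cosine, c(1, 0))
})

test_that("co-studied pairs never appear among repurposing candidates", {
  kg <- fixture_kg(seed = 3L, n_studies = 30L)
  emb <- train_transe(kg, train_config(dim = 16L, epochs = 30L, seed = 5L))
  excl <- co_studied_pairs(kg)
  cand <- repurposing_candidates(emb, kg, k = 50L)
  hit <- merge(cand, excl, by = c("condition", "drug"))
  expect_identical(nrow(hit), 0L)
  # a co-studied pair is excluded regardless of similarity rank
  expect_gt(nrow(excl), 0L)
  all_pairs <- topk_similar(emb, kg, "Condition", "DrugTerm",
                            k = .Machine$integer.max)$pairs
  expect_gt(nrow(all_pairs), nrow(cand))
})

test_that("conditions with shared drug neighborhoods embed similarly", {
  fx <- generate_fixture(fixture_config(n_studies = 30L, seed = 3L))
  kg <- assemble(fx$tables, fx$dict, fx$lexicon,
                 assemble_config(clusters = 4L, seed = 2L))
  emb <- train_transe(kg, train_config(dim = 16L, epochs = 40L, seed = 5L))
  motif <- fx$truth$motif
  expect_false(is.null(motif))
  res <- topk_similar(emb, kg, "Condition", "Condition",
                      k = .Machine$integer.max)
  pair <- res$pairs[
    (id_a == paste0("condition:", motif$c1) &
       id_b == paste0("condition:", motif$c2)) |
      (id_a == paste0("condition:", motif$c2) &
         id_b == paste0("condition:", motif$c1))]
  expect_identical(nrow(pair), 1L)
  expect_gt(pair$cosine, res$mean_similarity)
})
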