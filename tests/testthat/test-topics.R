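test_that("exact rank-1 input is recovered with near-zero objective", {
  R <- outer(c(1, 2, 3), c(2, 1, 0, 1))
  fit <- fit_nmf(R, k = 1, seed = 1)
  expect_lt(fit$objective, 1e-8)
  expect_true(all(fit$W >= 0) && all(fit$H >= 0))
})

test_that("objective is recomputed exactly and non-increasing over sweeps", {
  set.seed(2)
  R <- matrix(runif(40 * 15), 40, 15)
  fit <- suppressWarnings(fit_nmf(R, k = 4, seed = 9, max_iter = 80))
  recomputed <- 0.5 * sum((R - fit$W %*% fit$H)^2)
  expect_equal(fit$objective, recomputed, tolerance = 1e-9)
  expect_true(all(diff(fit$objective_trace) <= 1e-9 * fit$objective_trace[1]))
})

test_that("fit is deterministic for a fixed seed and errors when k exceeds min(n, m)", {
  R <- block_matrix()
  f1 <- fit_nmf(R, 3, seed = 7)
  f2 <- fit_nmf(R, 3, seed = 7)
  expect_identical(f1$W, f2$W)
  expect_identical(f1$H, f2$H)
  expect_error(fit_nmf(R[1:4, ], 5), "min\\(n, m\\)")
})

test_that("block-diagonal corpus puts each document on its block's topic", {
  R <- block_matrix(blocks = 3, docs_per_block = 6, terms_per_block = 5)
  fit <- fit_nmf(R, 3, seed = 21)
  a <- assign_documents(fit)
  block <- rep(1:3, each = 6)
  # documents of one block must share a topic, one topic per block
  tab <- table(block, a$topic_id)
  expect_true(all(rowSums(tab > 0) == 1))
  expect_equal(length(unique(a$topic_id)), 3)
})

test_that("top_terms ranks by weight with lexicographic ties and truncates depth", {
  model <- structure(list(
    W = matrix(1, 2, 2), H = rbind(c(0.9, 0.1, 0.5), c(0.2, 0.2, 0.2)),
    k = 2L, row_ids = c("d1", "d2"), lemmas = c("beta", "alpha", "gamma")
  ), class = "nmf_model")
  tt <- top_terms(model, topic_id = 0, depth = 2)
  expect_equal(tt$lemma, c("beta", "gamma"))
  ties <- top_terms(model, topic_id = 1, depth = 3)
  expect_equal(ties$lemma, c("alpha", "beta", "gamma"))
  expect_equal(nrow(top_terms(model, topic_id = 0, depth = 5)), 3)
  expect_error(top_terms(model, topic_id = 2), "topic_id")
})

test_that("document assignment takes the argmax with ties to the lowest topic", {
  model <- structure(list(
    W = rbind(c(0.1, 0.7, 0.2), c(0.5, 0.5, 0), c(0, 0, 0)),
    H = matrix(1, 3, 4), k = 3L,
    row_ids = c("d1", "d2", "d3"), lemmas = letters[1:4]
  ), class = "nmf_model")
  a <- assign_documents(model)
  expect_equal(a$topic_id, c(1L, 0L, NA))
  expect_equal(attr(a, "report")$n_unassigned, 1)
  # partition property: assigned + unassigned = n
  expect_equal(sum(!is.na(a$topic_id)) + sum(is.na(a$topic_id)), 3)
})

test_that("doc_topic_probability normalizes columns globally and flags dead topics", {
  model <- structure(list(
    W = cbind(c(2, 2, 0), c(1, 1, 2)), H = matrix(1, 2, 3), k = 2L,
    row_ids = c("d1", "d2", "d3"), lemmas = letters[1:3]
  ), class = "nmf_model")
  p <- doc_topic_probability(model)
  expect_equal(p$p[p$topic_id == 0], c(0.5, 0.5, 0))
  sums <- tapply(p$p, p$topic_id, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
  model$W[, 2] <- 0
  expect_error(doc_topic_probability(model), "degenerate")
})

test_that("average Jaccard over depths matches hand enumeration", {
  aj <- litprior:::average_jaccard
  expect_equal(aj(c("a", "b", "c"), c("a", "b", "c")), 1)
  # depths 1..3: 1, 1, 1/2 -> mean 5/6
  expect_equal(aj(c("a", "b", "c"), c("a", "b", "d")), (1 + 1 + 0.5) / 3)
  expect_equal(aj(c("a", "b"), c("x", "y")), 0)
})

test_that("Hungarian assignment matches brute-force enumeration", {
  set.seed(5)
  for (n in 2:5) {
    for (rep in 1:5) {
      cost <- matrix(runif(n * n), n)
      got <- litprior:::solve_assignment(cost)
      want <- brute_assignment(cost)
      expect_equal(sum(cost[cbind(seq_len(n), got)]), want$cost,
                   tolerance = 1e-12)
    }
  }
})

test_that("stability is 1 for identical rankings and in [0, 1] on data", {
  expect_equal(litprior:::matched_agreement(
    list(c("a", "b"), c("c", "d")), list(c("c", "d"), c("a", "b"))), 1)
  R <- block_matrix(blocks = 2, docs_per_block = 8, terms_per_block = 5)
  s <- topic_stability(R, k = 2, n_runs = 3, sample_frac = 0.8, depth = 3,
                       seed = 4, max_iter = 100)
  expect_gte(s, 0)
  expect_lte(s, 1)
})

test_that("symmetric KL divergence matches direct evaluation and is non-negative", {
  skl <- litprior:::symmetric_kl
  expect_equal(skl(c(0.5, 0.5), c(0.5, 0.5)), 0, tolerance = 1e-12)
  # direct evaluation of sum(u log u/v) + sum(v log v/u)
  u <- c(0.5, 0.5); v <- c(0.9, 0.1)
  direct <- sum(u * log(u / v)) + sum(v * log(v / u))
  expect_equal(skl(u, v), direct, tolerance = 1e-12)
  expect_equal(direct, 0.8789, tolerance = 1e-4)
  set.seed(8)
  for (i in 1:20) {
    a <- runif(5); b <- runif(5)
    expect_gte(skl(a, b), 0)
  }
})

test_that("divergence returns 0 with a warning for k = 1", {
  R <- outer(c(1, 2, 3), c(2, 1, 1))
  fit <- fit_nmf(R, 1)
  expect_warning(d <- arun_divergence(fit), "k = 1")
  expect_equal(d, 0)
})

test_that("a singleton k grid selects that k", {
  R <- block_matrix(blocks = 2, docs_per_block = 8, terms_per_block = 5)
  ks <- select_k(R, k_grid = 2, n_runs = 2, sample_frac = 0.8, depth = 3,
                 seed = 3, max_iter = 60)
  expect_equal(attr(ks, "k_selected"), 2)
  expect_equal(nrow(ks), 1)
})

test_that("select_k recovers a planted topic count on one synthetic corpus", {
  spec <- synthetic_spec(k_true = 4, seed = 401, profile_scale = 0.3)
  corp <- generate_corpus(spec)
  tok <- tokenize_abstracts(corp$records)
  tm <- build_tfidf(tok, build_vocabulary(tok))
  ks <- select_k(tm, k_grid = 2:7, n_runs = 4, sample_frac = 0.75, depth = 10,
                 seed = 1, max_iter = 200, tol = 1e-6)
  expect_equal(attr(ks, "k_selected"), 4)
})
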