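test_that("the same seed reproduces the corpus exactly", {
  spec <- synthetic_spec(k_true = 3, seed = 123, profile_scale = 0.2)
  c1 <- generate_corpus(spec)
  c2 <- generate_corpus(spec)
  expect_identical(c1$records, c2$records)
  expect_identical(c1$truth$assignments, c2$truth$assignments)
  c3 <- generate_corpus(synthetic_spec(k_true = 3, seed = 124,
                                       profile_scale = 0.2))
  expect_false(identical(c1$records$abstract, c3$records$abstract))
})

test_that("per-window counts track the expected intensities (law of large numbers)", {
  spec <- synthetic_spec(k_true = 3, seed = 3141, profile_scale = 4)
  corp <- generate_corpus(spec)
  expected <- corp$truth$spec$docs_per_window
  realized <- corp$truth$realized_counts
  # Poisson counts: |realized - expected| within 3 standard errors,
  # allowing the odd cell out at this many comparisons
  z <- abs(realized - expected) / sqrt(expected)
  expect_lt(mean(z > 3), 0.02)
  expect_equal(sum(realized), nrow(corp$records))
})

test_that("generated abstracts survive preprocessing with lemmas intact", {
  spec <- synthetic_spec(k_true = 3, seed = 9, profile_scale = 0.2)
  corp <- generate_corpus(spec)
  expect_true(all(nzchar(corp$records$abstract)))
  tok <- tokenize_abstracts(corp$records)
  expect_true(all(tok$n_tokens >= 1))
  # synthetic lemmas pass through the lemmatizer unchanged
  expect_true(all(grepl("^v[a-z]{3}x$", unlist(tok$tokens))))
})

test_that("dates fall inside each document's window and period", {
  spec <- synthetic_spec(k_true = 2, seed = 21, profile_scale = 0.15)
  corp <- generate_corpus(spec)
  w <- window_of(corp$records$pub_date, corp$truth$partition)
  expect_true(all(!is.na(w)))
  expect_true(all(corp$records$pub_date >= spec$period$start_date))
  expect_true(all(corp$records$pub_date <= spec$period$end_date))
})

test_that("planted coverage trends are detectable on the planted REC series", {
  # explicit expected counts: topic 0 ramps up linearly, topic 1 constant
  dpw <- rbind(seq(4, 40, length.out = 10), rep(20, 10))
  spec <- synthetic_spec(k_true = 2, docs_per_window = dpw, seed = 61)
  corp <- generate_corpus(spec)
  rec <- compute_rec(corp$truth$assignments, corp$records,
                     corp$truth$partition)
  series <- rec$rec[rec$topic_id == 0][order(rec$window_index[rec$topic_id == 0])]
  mk <- mann_kendall(series)
  expect_equal(mk$direction, "increasing")
  expect_true(mk$significant)
})

test_that("NMF on a sharp synthetic corpus recovers the planted topics", {
  spec <- synthetic_spec(k_true = 6, seed = 777, profile_scale = 0.25)
  corp <- generate_corpus(spec)
  tok <- tokenize_abstracts(corp$records)
  tm <- build_tfidf(tok, build_vocabulary(tok))
  fit <- suppressWarnings(fit_nmf(tm, 6, seed = 5, max_iter = 200))
  a <- assign_documents(fit)
  truth <- corp$truth$assignments
  joined <- merge(a, truth, by = "doc_id", suffixes = c("_fit", "_true"))
  tab <- table(joined$topic_id_true, joined$topic_id_fit)
  # greedy matching of planted to fitted topics by document overlap
  purity <- sum(apply(tab, 1, max)) / sum(tab)
  expect_gte(purity, 0.8)
})

test_that("the worked-example fixture reproduces its hand-computed tables", {
  fx <- worked_example_fixture()
  rpm <- rpm_table(fx$assignments, fx$probabilities, fx$records,
                   fx$partition, fx$outbreak_start)
  for (tbl in c("rec", "b", "entropy")) {
    exp_tbl <- fx$expected[[tbl]]
    col <- setdiff(names(exp_tbl), c("topic_id", "window_index"))
    got <- merge(as.data.frame(rpm), exp_tbl,
                 by = c("topic_id", "window_index"))
    expect_equal(got[[paste0(col, ".x")]], got[[paste0(col, ".y")]],
                 tolerance = 1e-12)
  }
})

test_that("infeasible specs are rejected", {
  expect_error(synthetic_spec(k_true = 1), "k_true")
  expect_error(
    synthetic_spec(k_true = 2,
                   docs_per_window = matrix(0, 2, 10)),
    "at least one expected document")
})
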