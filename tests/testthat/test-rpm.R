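test_that("window partition covers the period with calendar arithmetic", {
  p70 <- study_period("2020-01-24", "2020-04-02", "2019-12-12")
  w <- partition_windows(p70, w_days = 7)
  expect_equal(nrow(w), 10)
  expect_false(attr(w, "short_last"))
  # 24 Jan - 3 Sep 2020 spans 224 days inclusive -> exactly 32 windows
  pfull <- study_period("2020-01-24", "2020-09-03", "2019-12-12")
  wfull <- partition_windows(pfull, w_days = 7)
  expect_equal(nrow(wfull), 32)
  expect_false(attr(wfull, "short_last"))
  # a 23-day period leaves a 2-day final window, which is flagged
  pshort <- study_period("2020-01-24", "2020-02-15", "2019-12-12")
  wshort <- partition_windows(pshort, w_days = 7)
  expect_equal(nrow(wshort), 4)
  expect_true(attr(wshort, "short_last"))
  # windows contiguous and non-overlapping
  expect_equal(wfull$start[-1], wfull$end[-nrow(wfull)])
  # fixed n_windows is honored; later documents fall outside
  w10 <- partition_windows(pfull, w_days = 7, n_windows = 10)
  expect_equal(nrow(w10), 10)
  expect_true(is.na(window_of(as.Date("2020-09-01"), w10)))
  expect_error(partition_windows(p70, w_days = 7, n_windows = 30),
               "no overlap")
})

test_that("dates on window boundaries belong to the later window", {
  p <- study_period("2020-01-24", "2020-02-20", "2019-12-12")
  w <- partition_windows(p, w_days = 7)
  expect_equal(window_of(as.Date("2020-01-24"), w), 1L)
  expect_equal(window_of(as.Date("2020-01-30"), w), 1L)
  expect_equal(window_of(as.Date("2020-01-31"), w), 2L)
  expect_true(is.na(window_of(as.Date("2020-01-23"), w)))
})

test_that("REC counts topic shares per window", {
  p <- study_period("2020-01-24", "2020-02-06", "2019-12-12")
  w <- partition_windows(p, w_days = 7)
  recs <- make_records(n = 4, dates = rep(as.Date("2020-01-25"), 4))
  assign <- tibble::tibble(doc_id = recs$doc_id,
                           topic_id = c(0L, 0L, 0L, 1L))
  rec <- compute_rec(assign, recs, w)
  expect_equal(rec$rec[rec$topic_id == 0 & rec$window_index == 1], 0.75)
  expect_equal(rec$rec[rec$topic_id == 1 & rec$window_index == 1], 0.25)
  # empty window flagged as missing
  expect_true(all(is.na(rec$rec[rec$window_index == 2])))
  expect_equal(attr(rec, "report")$empty_windows, 2L)
})

test_that("single-topic corpus has REC 1 in every non-empty window", {
  p <- study_period("2020-01-24", "2020-02-06", "2019-12-12")
  w <- partition_windows(p, w_days = 7)
  recs <- make_records(n = 6, dates = as.Date("2020-01-24") + c(0, 2, 4, 7, 9, 12))
  assign <- tibble::tibble(doc_id = recs$doc_id, topic_id = 0L)
  rec <- compute_rec(assign, recs, w)
  expect_true(all(rec$rec == 1))
})

test_that("Mann-Kendall matches the worked example and handles ties", {
  mk <- mann_kendall(1:10)
  expect_equal(mk$s_stat, 45L)
  expect_equal(mk$var_s, 125)
  expect_equal(mk$z_mk, 44 / sqrt(125), tolerance = 1e-12)
  expect_true(mk$significant)
  expect_equal(mk$direction, "increasing")

  const <- mann_kendall(rep(2, 8))
  expect_equal(const$s_stat, 0L)
  expect_equal(const$z_mk, 0)
  expect_equal(const$direction, "none")
  expect_false(const$significant)
})

test_that("reversing a series flips the sign of Z (antisymmetry)", {
  set.seed(31)
  for (i in 1:10) {
    x <- sample(1:5, 9, replace = TRUE)
    expect_equal(mann_kendall(rev(x))$z_mk, -mann_kendall(x)$z_mk,
                 tolerance = 1e-12)
  }
})

test_that("short series are flagged, not significant", {
  mk <- mann_kendall(c(1, 2, 3))
  expect_true(mk$too_short)
  expect_false(mk$significant)
})

test_that("time distance averages day gaps and bounds within the window", {
  p <- study_period("2020-01-24", "2020-02-06", "2019-12-12")
  w <- partition_windows(p, w_days = 7)
  outbreak <- p$outbreak_start
  recs <- make_records(n = 2, dates = outbreak + c(44, 49))
  assign <- tibble::tibble(doc_id = recs$doc_id, topic_id = 0L)
  b <- time_distance(assign, recs, w, outbreak)
  expect_equal(b$b_days[b$window_index == 1], 46.5)
  # bounding: B lies inside the window's day range from the outbreak
  expect_gte(b$b_days[b$window_index == 1], 43)
  expect_lt(b$b_days[b$window_index == 1], 50)
  # pre-outbreak publication violates the model
  early <- make_records(n = 1, dates = as.Date("2019-12-01"))
  expect_error(
    time_distance(tibble::tibble(doc_id = "r001", topic_id = 0L),
                  early, w, outbreak),
    "precede")
})

test_that("publication on the outbreak day is offset to one day", {
  p <- study_period("2019-12-12", "2019-12-18", "2019-12-12")
  w <- partition_windows(p, w_days = 7)
  recs <- make_records(n = 1, dates = as.Date("2019-12-12"))
  assign <- tibble::tibble(doc_id = "r001", topic_id = 0L)
  b <- time_distance(assign, recs, w, p$outbreak_start)
  expect_equal(b$b_days[1], 1)
})

test_that("topic entropy renormalizes within the cell", {
  p <- study_period("2020-01-24", "2020-02-06", "2019-12-12")
  w <- partition_windows(p, w_days = 7)
  recs <- make_records(n = 7, dates = c(rep(as.Date("2020-01-25"), 4),
                                        rep(as.Date("2020-02-01"), 3)))
  assign <- tibble::tibble(doc_id = recs$doc_id, topic_id = 0L)
  probs <- tibble::tibble(doc_id = recs$doc_id, topic_id = 0L,
                          p = c(rep(0.1, 4), 0.3, 0.15, 0.15))
  e <- topic_entropy(probs, assign, recs, w)
  # four docs with equal mass -> ln 4
  expect_equal(e$entropy[e$window_index == 1], log(4), tolerance = 1e-12)
  # q = (0.5, 0.25, 0.25) -> 1.0397
  expect_equal(e$entropy[e$window_index == 2],
               -(0.5 * log(0.5) + 0.5 * log(0.25)), tolerance = 1e-12)
})

test_that("singleton and dominated cells degrade gracefully", {
  p <- study_period("2020-01-24", "2020-02-06", "2019-12-12")
  w <- partition_windows(p, w_days = 7)
  recs <- make_records(n = 3, dates = c(as.Date("2020-01-25"),
                                        rep(as.Date("2020-02-01"), 2)))
  assign <- tibble::tibble(doc_id = recs$doc_id, topic_id = 0L)
  probs <- tibble::tibble(doc_id = recs$doc_id, topic_id = 0L,
                          p = c(0.5, 0.5 - 1e-12, 1e-12))
  e <- topic_entropy(probs, assign, recs, w)
  expect_equal(e$entropy[e$window_index == 1], 0)  # singleton cell
  expect_true(e$small_cell[e$window_index == 1])
  expect_lt(e$entropy[e$window_index == 2], 1e-9)  # one dominant doc
})

test_that("RRR divides window mass by B * E and scales inversely with both", {
  fx <- worked_example_fixture()
  b <- time_distance(fx$assignments, fx$records, fx$partition,
                     fx$outbreak_start)
  e <- topic_entropy(fx$probabilities, fx$assignments, fx$records,
                     fx$partition)
  r <- compute_rrr(b, fx$probabilities, e, fx$assignments, fx$records,
                   fx$partition)
  cell <- r[r$topic_id == 0 & r$window_index == 2, ]
  expect_equal(cell$rrr, 0.2 / (50 * log(4)), tolerance = 1e-12)
  # doubling B halves RRR, holding mass and entropy fixed
  b2 <- b; b2$b_days <- b2$b_days * 2
  r2 <- compute_rrr(b2, fx$probabilities, e, fx$assignments, fx$records,
                    fx$partition)
  expect_equal(r2$rrr, r$rrr / 2, tolerance = 1e-12)
  expect_true(all(r$rrr[!is.na(r$rrr)] >= 0))
  # singleton cell -> entropy 0 -> missing, flagged
  sing <- r[r$topic_id == 1 & r$window_index == 1, ]
  expect_true(is.na(sing$rrr))
  expect_equal(sing$flag, "small_cell")
})

test_that("per-window REC sums plus the unassigned share conserve to 1", {
  spec <- synthetic_spec(k_true = 3, seed = 77, profile_scale = 0.2)
  corp <- generate_corpus(spec)
  # knock two documents into the unassigned bucket
  assign <- corp$truth$assignments
  assign$topic_id[1:2] <- NA
  rec <- compute_rec(assign, corp$records, corp$truth$partition)
  per_window <- tapply(rec$rec, rec$window_index, sum)
  counts <- table(factor(
    litprior::window_of(corp$records$pub_date, corp$truth$partition),
    levels = corp$truth$partition$window_index))
  unassigned_share <- sapply(corp$truth$partition$window_index, function(wi) {
    idx <- which(litprior::window_of(corp$records$pub_date,
                                     corp$truth$partition) == wi)
    if (length(idx) == 0) return(NA_real_)
    mean(is.na(assign$topic_id[idx]))
  })
  ok <- !is.na(per_window)
  expect_equal(as.numeric(per_window[ok] + unassigned_share[ok]),
               rep(1, sum(ok)), tolerance = 1e-12)
})
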