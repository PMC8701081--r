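#' Specification of a synthetic literature stream
#'
#' Describes a corpus with planted structure at every level the pipeline
#' later estimates: `k_true` topic-word distributions drawn from a
#' symmetric Dirichlet (`topic_sharpness` is the concentration; small
#' values give sharp, well-separated topics), expected per-topic
#' per-window document counts encoding the temporal archetypes and
#' coverage trends, and publication dates placed inside 7-day windows.
#'
#' Per-topic `profiles` select built-in expected-count shapes whose
#' deterministic RRR trajectories realize the three archetypes:
#' `"emergency"` (RRR peaks in window 1, then decays), `"persistent"`
#' (peaks in window 2, slow decline), `"fluctuating"` (alternating
#' high/low response). `trend` overlays a multiplicative ramp to tilt a
#' topic's share of output (`"increasing"`, `"stable"`, `"decreasing"`).
#' An explicit `docs_per_window` matrix (topics x windows) overrides both.
#'
#' @param k_true Number of planted topics (>= 2).
#' @param vocab_size Number of synthetic lemmas.
#' @param topic_sharpness Dirichlet concentration of topic-word
#'   distributions.
#' @param doc_length Mean tokens per abstract (Poisson, floored at 10).
#' @param profiles Character vector of archetypes, recycled to `k_true`.
#' @param trend Character vector of coverage trends, recycled to `k_true`.
#' @param docs_per_window Optional explicit expected-count matrix.
#' @param profile_scale Multiplier on the built-in expected counts.
#' @param period A [study_period()]; defaults to 70 days from 24 Jan 2020
#'   (ten 7-day windows) anchored at the 12 Dec 2019 outbreak start.
#' @param w_days,n_windows Window geometry for the planted profiles.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(k_true = 6,
                           vocab_size = 400,
                           topic_sharpness = 0.05,
                           doc_length = 60,
                           profiles = c("emergency", "persistent",
                                        "fluctuating"),
                           trend = "stable",
                           docs_per_window = NULL,
                           profile_scale = 1,
                           period = study_period("2020-01-24", "2020-04-02",
                                                 "2019-12-12"),
                           w_days = 7,
                           n_windows = 10,
                           seed = 42L) {
  stopifnot(k_true >= 2, vocab_size >= 10, topic_sharpness > 0,
            doc_length >= 10)
  profiles <- rep_len(profiles, k_true)
  trend <- rep_len(trend, k_true)
  if (is.null(docs_per_window)) {
    docs_per_window <- t(vapply(seq_len(k_true), function(t) {
      archetype_counts(profiles[t], n_windows) * profile_scale *
        trend_ramp(trend[t], n_windows)
    }, numeric(n_windows)))
  } else {
    docs_per_window <- as.matrix(docs_per_window)
    stopifnot(nrow(docs_per_window) == k_true, all(docs_per_window >= 0))
    n_windows <- ncol(docs_per_window)
  }
  if (any(rowSums(docs_per_window) < 1)) {
    stop("every topic needs at least one expected document", call. = FALSE)
  }
  structure(
    list(k_true = as.integer(k_true), vocab_size = as.integer(vocab_size),
         topic_sharpness = topic_sharpness, doc_length = doc_length,
         profiles = profiles, trend = trend,
         docs_per_window = docs_per_window,
         period = period, w_days = w_days, n_windows = as.integer(n_windows),
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Expected-count archetypes over n windows. The shapes are calibrated so
# that, with dates uniform in 7-day windows anchored 43 days after the
# outbreak start, the deterministic RRR trajectory of each archetype
# carries its label: emergency peaks in window 1 with ~1.8x margin over
# window 2 and decays smoothly (detrended CV ~0.33); persistent peaks in
# window 2; fluctuating alternates high/low (8 material sign changes).
archetype_counts <- function(profile, n_windows) {
  w <- seq_len(n_windows)
  base <- switch(profile,
    emergency = 34 + 56 * c(1, 0.29, 0.20, 0.14, 0.11, 0.07, 0.05, 0.04,
                            0.02, 0)[pmin(w, 10)],
    persistent = {
      out <- 38 + 42 * c(0, 1, 0.52, 0.33, 0.21, 0.14, 0.10, 0.05, 0.02,
                         0)[pmin(w, 10)]
      out[1] <- 25
      out
    },
    fluctuating = ifelse(w %% 2 == 1, 70 - 2.5 * (w - 1), 12 - 0.5 * (w - 2)),
    stop("unknown profile: ", profile, call. = FALSE)
  )
  pmax(base, 4)
}

trend_ramp <- function(trend, n_windows) {
  w <- seq_len(n_windows)
  slope <- switch(trend,
    increasing = 0.08, decreasing = -0.08, stable = 0,
    stop("unknown trend: ", trend, call. = FALSE))
  pmax(1 + slope * (w - (n_windows + 1) / 2), 0.05)
}

# Synthetic lemma strings: pure letters, ending in "x" so the rule
# lemmatizer leaves them alone, never colliding with the stop list.
synthetic_vocab <- function(vocab_size) {
  need <- vocab_size
  combos <- expand.grid(a = letters, b = letters, c = letters,
                        stringsAsFactors = FALSE)
  if (need > nrow(combos)) stop("vocab_size too large", call. = FALSE)
  paste0("v", combos$a[seq_len(need)], combos$b[seq_len(need)],
         combos$c[seq_len(need)], "x")
}

#' Generate a synthetic corpus with planted ground truth
#'
#' Draws per-cell document counts as Poisson around the spec's expected
#' counts, samples each document's tokens from its topic's word
#' distribution, and places publication dates uniformly within the
#' document's window. Fully reproducible from `spec$seed`.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `records` (a tibble usable everywhere a
#'   [read_metadata()] result is) and `truth`: `assignments` (planted
#'   doc-topic labels), `probabilities` (uniform ground-truth `p(d|t)`
#'   over each topic's documents), `topic_word` (k x V matrix),
#'   `profiles`, `trend`, `expected_counts`, `partition`, and the spec.
#' @export
generate_corpus <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(spec$seed)

  vocab <- synthetic_vocab(spec$vocab_size)
  k <- spec$k_true
  topic_word <- matrix(stats::rgamma(k * spec$vocab_size,
                                     shape = spec$topic_sharpness),
                       nrow = k)
  topic_word <- topic_word / rowSums(topic_word)
  dimnames(topic_word) <- list(NULL, vocab)

  partition <- partition_windows(spec$period, w_days = spec$w_days,
                                 n_windows = spec$n_windows)
  counts <- matrix(stats::rpois(length(spec$docs_per_window),
                                lambda = spec$docs_per_window),
                   nrow = k)

  topic_id <- integer(0); window_index <- integer(0)
  for (t in seq_len(k)) {
    for (w in seq_len(spec$n_windows)) {
      n_tw <- counts[t, w]
      if (n_tw > 0) {
        topic_id <- c(topic_id, rep.int(t - 1L, n_tw))
        window_index <- c(window_index, rep.int(w, n_tw))
      }
    }
  }
  n_docs <- length(topic_id)
  if (n_docs == 0) stop("spec generated an empty corpus", call. = FALSE)

  win_len <- as.integer(partition$end - partition$start)
  offset <- floor(stats::runif(n_docs) * win_len[window_index])
  pub_date <- partition$start[window_index] + offset

  lens <- pmax(stats::rpois(n_docs, spec$doc_length), 10L)
  abstracts <- vapply(seq_len(n_docs), function(i) {
    toks <- sample(vocab, lens[i], replace = TRUE,
                   prob = topic_word[topic_id[i] + 1L, ])
    paste(toks, collapse = " ")
  }, character(1))

  doc_id <- sprintf("syn%06d", seq_len(n_docs))
  records <- tibble::tibble(
    doc_id = doc_id, title = NA_character_, abstract = abstracts,
    pub_date = pub_date, language_tag = "en"
  )
  assignments <- tibble::tibble(doc_id = doc_id, topic_id = topic_id)
  probabilities <- assignments |>
    dplyr::group_by(.data$topic_id) |>
    dplyr::mutate(p = 1 / dplyr::n()) |>
    dplyr::ungroup()

  list(
    records = records,
    truth = list(
      assignments = assignments,
      probabilities = probabilities,
      topic_word = topic_word,
      profiles = spec$profiles,
      trend = spec$trend,
      expected_counts = spec$docs_per_window,
      realized_counts = counts,
      partition = partition,
      spec = spec
    )
  )
}

#' Write a synthetic corpus as JSONL plus a ground-truth sidecar
#'
#' Emits the JSONL dialect [read_metadata()] reads and a JSON sidecar
#' with the planted assignments and archetypes.
#'
#' @param corpus A [generate_corpus()] result.
#' @param stem Output path stem (writes `<stem>.jsonl` and
#'   `<stem>-truth.json`).
#' @return `stem`, invisibly.
#' @export
write_synthetic_corpus <- function(corpus, stem) {
  recs <- corpus$records
  lines <- vapply(seq_len(nrow(recs)), function(i) {
    jsonlite::toJSON(list(
      doc_id = recs$doc_id[i], title = recs$title[i],
      abstract = recs$abstract[i],
      pub_date = format(recs$pub_date[i]),
      language_tag = recs$language_tag[i]
    ), auto_unbox = TRUE, null = "null", na = "null")
  }, character(1))
  writeLines(lines, paste0(stem, ".jsonl"))
  jsonlite::write_json(
    list(assignments = corpus$truth$assignments,
         profiles = corpus$truth$profiles,
         trend = corpus$truth$trend),
    paste0(stem, "-truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(stem)
}

#' Tiny frozen corpus with hand-computed metric tables
#'
#' A 10-document, 2-topic, 2-window corpus with hard-coded topic
#' assignments, membership probabilities and publication dates, together
#' with its REC, research time distance, topic entropy and RRR tables
#' computed by hand from the definitions. It serves as a regression
#' fixture: the pipeline's metric functions must reproduce the `expected`
#' tables exactly (to numerical precision).
#'
#' Layout (outbreak 2019-12-12; windows of 7 days from 2020-01-24):
#' topic 0 has three window-1 documents at days 45/47/49 with membership
#' mass 0.4/0.2/0.2 and four window-2 documents at day 50 with mass 0.05
#' each; topic 1 has one window-1 document (day 44, mass 0.4 — a
#' singleton cell, so its entropy is 0 and its RRR undefined) and two
#' window-2 documents at day 53 with mass 0.3 each.
#'
#' @return A list with `records`, `assignments`, `probabilities`,
#'   `period`, `partition`, `outbreak_start`, and `expected` (tibbles
#'   `rec`, `b`, `entropy`, `rrr`).
#' @export
worked_example_fixture <- function() {
  period <- study_period("2020-01-24", "2020-02-06", "2019-12-12")
  partition <- partition_windows(period, w_days = 7, n_windows = 2)
  outbreak <- period$outbreak_start

  doc_id <- sprintf("f%02d", 1:10)
  days <- c(45, 47, 49, 50, 50, 50, 50, 44, 53, 53)
  topic <- c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 1L, 1L, 1L)
  p <- c(0.4, 0.2, 0.2, 0.05, 0.05, 0.05, 0.05, 0.4, 0.3, 0.3)
  records <- tibble::tibble(
    doc_id = doc_id, title = NA_character_,
    abstract = paste("worked example document", doc_id),
    pub_date = outbreak + days, language_tag = "en"
  )
  assignments <- tibble::tibble(doc_id = doc_id, topic_id = topic)
  probabilities <- tibble::tibble(doc_id = doc_id, topic_id = topic, p = p)

  # Hand computations from the definitions:
  #   window 1 holds docs 1-3 (topic 0) and 8 (topic 1); window 2 holds
  #   docs 4-7 (topic 0) and 9-10 (topic 1).
  e_A1 <- -(0.5 * log(0.5) + 0.25 * log(0.25) + 0.25 * log(0.25))
  expected <- list(
    rec = tibble::tibble(
      topic_id = c(0L, 0L, 1L, 1L), window_index = c(1L, 2L, 1L, 2L),
      rec = c(3 / 4, 4 / 6, 1 / 4, 2 / 6)),
    b = tibble::tibble(
      topic_id = c(0L, 0L, 1L, 1L), window_index = c(1L, 2L, 1L, 2L),
      b_days = c(47, 50, 44, 53)),
    entropy = tibble::tibble(
      topic_id = c(0L, 0L, 1L, 1L), window_index = c(1L, 2L, 1L, 2L),
      entropy = c(e_A1, log(4), 0, log(2))),
    rrr = tibble::tibble(
      topic_id = c(0L, 0L, 1L, 1L), window_index = c(1L, 2L, 1L, 2L),
      rrr = c(0.8 / (47 * e_A1), 0.2 / (50 * log(4)), NA,
              0.6 / (53 * log(2))))
  )
  list(records = records, assignments = assignments,
       probabilities = probabilities, period = period,
       partition = partition, outbreak_start = outbreak,
       expected = expected)
}
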