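#' Top-weight keywords of each topic
#'
#' The hotspot keywords of a topic are the lemmas with the largest weights
#' in its row of `H`. Ties are broken lexicographically by lemma.
#'
#' @param model An `nmf_model`.
#' @param topic_id Integer topic id(s) in `0:(k-1)`, or `NULL` (default)
#'   for all topics.
#' @param depth How many keywords per topic (default 5, the conventional
#'   hotspot-keyword depth); silently truncated to the vocabulary size.
#' @return Tibble with columns `topic_id`, `rank`, `lemma`, `weight`,
#'   sorted by descending weight within topic.
#' @export
top_terms <- function(model, topic_id = NULL, depth = 5) {
  stopifnot(inherits(model, "nmf_model"))
  ids <- if (is.null(topic_id)) seq_len(model$k) - 1L else as.integer(topic_id)
  if (any(ids < 0 | ids >= model$k)) {
    stop("topic_id must lie in 0:", model$k - 1L, call. = FALSE)
  }
  depth <- min(depth, ncol(model$H))
  purrr::map_dfr(ids, function(t) {
    w <- model$H[t + 1L, ]
    ord <- order(-w, model$lemmas, method = "radix")[seq_len(depth)]
    tibble::tibble(
      topic_id = t, rank = seq_len(depth),
      lemma = model$lemmas[ord], weight = w[ord]
    )
  })
}

#' Ranked top-term list of one topic (internal helper)
#' @noRd
top_term_vector <- function(H, lemmas, t, depth) {
  w <- H[t, ]
  ord <- order(-w, lemmas, method = "radix")[seq_len(min(depth, length(w)))]
  lemmas[ord]
}

#' Assign each document to its dominant topic
#'
#' A document belongs to the topic with the largest entry of its row of
#' `W` (ties to the lowest topic id). Documents with an all-zero row
#' cannot be placed and receive `topic_id = NA`, excluded from every
#' topic's document set and counted in the attached report.
#'
#' @param model An `nmf_model`.
#' @return Tibble with columns `doc_id`, `topic_id` (0-based, `NA` for
#'   unassigned), and attribute `"report"` with the unassigned count.
#' @export
assign_documents <- function(model) {
  stopifnot(inherits(model, "nmf_model"))
  W <- model$W
  zero <- rowSums(W) == 0
  topic <- max.col(W, ties.method = "first") - 1L
  topic[zero] <- NA_integer_
  out <- tibble::tibble(doc_id = model$row_ids, topic_id = topic)
  attr(out, "report") <- list(n_unassigned = sum(zero))
  out
}

#' Per-topic document membership probabilities
#'
#' `p(d | t)` is the document's share of topic t's total weight:
#' column t of `W` normalized to sum 1 over all documents. These global
#' probabilities are the masses that the response-rate numerator sums
#' within each window.
#'
#' @param model An `nmf_model`.
#' @return Tibble with columns `doc_id`, `topic_id`, `p`; `sum(p)` is 1
#'   within each topic.
#' @export
doc_topic_probability <- function(model) {
  stopifnot(inherits(model, "nmf_model"))
  W <- model$W
  cs <- colSums(W)
  if (any(cs == 0)) {
    stop("degenerate topic(s) with all-zero weight column: ",
         paste(which(cs == 0) - 1L, collapse = ", "), call. = FALSE)
  }
  P <- sweep(W, 2, cs, "/")
  tibble::tibble(
    doc_id = rep(model$row_ids, times = model$k),
    topic_id = rep(seq_len(model$k) - 1L, each = nrow(W)),
    p = as.vector(P)
  )
}

# Average-Jaccard agreement between two ranked term lists: the mean over
# d = 1..depth of the set-Jaccard of their depth-d prefixes (Greene's
# average term stability, reported as agreement: 1 = identical rankings).
average_jaccard <- function(a, b) {
  depth <- min(length(a), length(b))
  if (depth == 0) return(0)
  mean(vapply(seq_len(depth), function(d) {
    ia <- a[seq_len(d)]; ib <- b[seq_len(d)]
    length(intersect(ia, ib)) / length(union(ia, ib))
  }, numeric(1)))
}

# Hungarian algorithm (potentials + augmenting paths) for the square
# min-cost assignment problem. Returns the column matched to each row.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n == m)
  INF <- .Machine$double.xmax / 4
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)            # p[j] = row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[m + 1] <- i                # virtual column m+1 holds the new row
    j0 <- m + 1L
    minv <- rep(INF, m)
    used <- logical(m + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j]) {
          cur <- cost[i0, j] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in seq_len(m + 1)) {
        if (used[j]) {
          if (p[j] > 0) u[p[j]] <- u[p[j]] + delta
          v[j] <- v[j] - delta
        } else {
          minv[j] <- minv[j] - delta
        }
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  match_for_row <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0) match_for_row[p[j]] <- j
  match_for_row
}

# Mean matched agreement between the topics of two models' H factors.
matched_agreement <- function(ref_terms, run_terms) {
  k <- length(ref_terms)
  agree <- matrix(0, k, k)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      agree[a, b] <- average_jaccard(ref_terms[[a]], run_terms[[b]])
    }
  }
  perm <- solve_assignment(1 - agree)
  mean(agree[cbind(seq_len(k), perm)])
}

#' Topic-structure stability across document subsamples
#'
#' Fits a reference model on all documents, then `n_runs` models on random
#' subsets of `sample_frac` of the documents, matches each run's topics to
#' the reference topics by maximizing total average-Jaccard agreement of
#' their top-`depth` term rankings (Hungarian assignment), and returns the
#' mean matched agreement. 1 means every run reproduces the reference
#' topic structure exactly; values near 0 mean the structure is not
#' reproducible and k is likely wrong.
#'
#' @param R A `term_matrix` or non-negative matrix.
#' @param k Number of topics.
#' @param n_runs Number of subsample fits (>= 2).
#' @param sample_frac Fraction of documents per subsample (0 < f <= 1).
#' @param depth Ranking depth for the average-Jaccard agreement.
#' @param seed Integer seed (controls subsampling and subsample inits).
#' @param max_iter,tol Passed to [fit_nmf()].
#' @param reference Optionally a pre-fitted reference `nmf_model` (reused
#'   by [select_k()] to avoid refitting).
#' @return A single number in `[0, 1]`.
#' @references Greene, O'Callaghan & Cunningham's term-stability approach
#'   to topic-number selection.
#' @export
topic_stability <- function(R, k, n_runs = 10, sample_frac = 0.8, depth = 10,
                            seed = 42L, max_iter = 200L, tol = 1e-6,
                            reference = NULL) {
  if (n_runs < 2) stop("n_runs must be at least 2", call. = FALSE)
  if (sample_frac <= 0 || sample_frac > 1) {
    stop("sample_frac must lie in (0, 1]", call. = FALSE)
  }
  dense <- as_dense_matrix(R)
  n <- nrow(dense)
  if (is.null(reference)) {
    reference <- fit_nmf(dense, k, seed = seed, max_iter = max_iter, tol = tol)
  }
  lemmas <- reference$lemmas
  ref_terms <- lapply(seq_len(k), function(t)
    top_term_vector(reference$H, lemmas, t, depth))

  n_sub <- max(k, ceiling(sample_frac * n))
  if (n_sub > n) stop("subsample smaller than k", call. = FALSE)

  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  run_seeds <- sample.int(2^31 - 1, n_runs)
  scores <- vapply(seq_len(n_runs), function(r) {
    idx <- sample.int(n, n_sub)
    fit <- suppressWarnings(
      fit_nmf(dense[idx, , drop = FALSE], k, seed = run_seeds[r],
              max_iter = max_iter, tol = tol, init = "random")
    )
    run_terms <- lapply(seq_len(k), function(t)
      top_term_vector(fit$H, lemmas, t, depth))
    matched_agreement(ref_terms, run_terms)
  }, numeric(1))
  mean(scores)
}

#' Symmetric KL divergence between factor spectra (topic-count diagnostic)
#'
#' Compares the singular-value distribution of `H` with the column-l2-norm
#' distribution of `W` (both sorted descending and normalized to sum 1)
#' by symmetric Kullback-Leibler divergence. When k matches the latent
#' topic count the two spectra agree and the divergence is small; an
#' epsilon floor of 1e-12 guards zero components.
#'
#' @param model An `nmf_model`.
#' @param R Unused; accepted for interface symmetry with
#'   [topic_stability()].
#' @return Non-negative number; 0 by convention (with a warning) for k = 1.
#' @references Arun et al.'s spectral diagnostic for choosing the number
#'   of topics in matrix-factorization models.
#' @export
arun_divergence <- function(model, R = NULL) {
  stopifnot(inherits(model, "nmf_model"))
  if (model$k == 1) {
    warning("divergence undefined for k = 1; returning 0", call. = FALSE)
    return(0)
  }
  u <- sort(svd(model$H, nu = 0, nv = 0)$d, decreasing = TRUE)
  v <- sort(sqrt(colSums(model$W^2)), decreasing = TRUE)
  symmetric_kl(u, v)
}

symmetric_kl <- function(u, v, eps = 1e-12) {
  u <- pmax(u, eps); v <- pmax(v, eps)
  u <- u / sum(u); v <- v / sum(v)
  sum(u * log(u / v)) + sum(v * log(v / u))
}

#' Select the number of topics over a grid
#'
#' Computes the stability and divergence diagnostics for each candidate k
#' and selects the largest k whose stability lies within
#' `stability_margin` of the best stability on the grid. The rationale:
#' below the latent topic count, merged topics reproduce stably across
#' document subsamples, so stability stays on a high plateau; one step
#' past it, a topic must split arbitrarily and stability collapses. The
#' selected k is therefore the end of the plateau — the finest structure
#' that is still reproducible. (When several k are comparably stable,
#' preferring the finer structure also matches how a larger corpus's
#' candidate counts are adjudicated by inspecting the topics themselves.)
#'
#' The full grid is returned so the choice can be overridden by
#' inspection; the divergence column is reported as a complementary
#' diagnostic but does not enter the automatic rule, because its value is
#' near-degenerate for very small k and would drag the selection there.
#'
#' @param R A `term_matrix` or non-negative matrix.
#' @param k_grid Candidate topic counts (default `5:30`, the conventional
#'   screening range for a large corpus).
#' @param n_runs,sample_frac,depth Stability settings; see
#'   [topic_stability()].
#' @param seed Integer seed.
#' @param max_iter,tol Passed to [fit_nmf()].
#' @param stability_margin How far below the grid's best stability a
#'   candidate may fall and still count as on the plateau.
#' @return A tibble of class `k_selection` with columns `k`, `stability`,
#'   `divergence`, `on_plateau`, and attribute `k_selected`.
#' @export
select_k <- function(R, k_grid = 5:30, n_runs = 10, sample_frac = 0.8,
                     depth = 10, seed = 42L, max_iter = 200L, tol = 1e-6,
                     stability_margin = 0.05) {
  if (any(k_grid < 2)) stop("k candidates must be >= 2", call. = FALSE)
  dense <- as_dense_matrix(R)
  rows <- purrr::map(k_grid, function(k) {
    tryCatch({
      ref <- suppressWarnings(
        fit_nmf(dense, k, seed = seed, max_iter = max_iter, tol = tol))
      stab <- topic_stability(dense, k, n_runs = n_runs,
                              sample_frac = sample_frac, depth = depth,
                              seed = seed + k, max_iter = max_iter, tol = tol,
                              reference = ref)
      div <- arun_divergence(ref)
      tibble::tibble(k = k, stability = stab, divergence = div)
    }, error = function(e) {
      warning("k = ", k, " skipped: ", conditionMessage(e), call. = FALSE)
      tibble::tibble(k = k, stability = NA_real_, divergence = NA_real_)
    })
  })
  out <- dplyr::bind_rows(rows)
  ok <- !is.na(out$stability)
  if (!any(ok)) stop("no candidate k could be fitted", call. = FALSE)
  best <- max(out$stability[ok])
  out$on_plateau <- ok & out$stability >= best - stability_margin
  attr(out, "k_selected") <- max(out$k[out$on_plateau])
  class(out) <- c("k_selection", class(out))
  out
}

#' @exportS3Method base::print
print.k_selection <- function(x, ...) {
  cat("<k_selection> grid ", min(x$k), "..", max(x$k),
      ", selected k = ", attr(x, "k_selected"), "\n", sep = "")
  NextMethod()
}

#' Write topic-number diagnostics as CSV
#'
#' @param x A `k_selection` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_k_selection <- function(x, path) {
  utils::write.csv(as.data.frame(x)[, c("k", "stability", "divergence")],
                   path, row.names = FALSE)
  invisible(path)
}
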