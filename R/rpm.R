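#' Partition a study period into time-windows
#'
#' Builds contiguous, non-overlapping, half-open windows
#' `[start, start + w_days)` beginning at the period's start date. With
#' `n_windows = NULL` the windows cover the whole period (the last one may
#' be short, which is flagged); with a fixed `n_windows` exactly that many
#' are produced and later documents are excluded downstream with a report.
#'
#' @param period A [study_period()].
#' @param w_days Window length in days (default 7).
#' @param n_windows Number of windows, or `NULL` to cover the period.
#' @return Tibble of class `window_partition` with columns `window_index`
#'   (1-based), `start`, `end` (exclusive); attributes `w_days` and
#'   `short_last`.
#' @export
partition_windows <- function(period, w_days = 7, n_windows = NULL) {
  stopifnot(inherits(period, "study_period"), w_days >= 1)
  total_days <- as.integer(period$end_date - period$start_date) + 1L
  if (is.null(n_windows)) {
    n_windows <- ceiling(total_days / w_days)
  } else {
    n_windows <- as.integer(n_windows)
    if (n_windows < 1) stop("n_windows must be >= 1", call. = FALSE)
    # the last window must overlap the period by at least one day
    if ((n_windows - 1L) * w_days >= total_days) {
      stop("requested windows extend past the study period with no overlap",
           call. = FALSE)
    }
  }
  starts <- period$start_date + (seq_len(n_windows) - 1L) * w_days
  ends <- pmin(starts + w_days, period$end_date + 1L)
  out <- tibble::tibble(
    window_index = seq_len(n_windows), start = starts, end = ends
  )
  attr(out, "w_days") <- w_days
  attr(out, "short_last") <- as.integer(ends[n_windows] - starts[n_windows]) < w_days
  class(out) <- c("window_partition", class(out))
  out
}

#' Locate dates in a window partition
#'
#' @param dates A `Date` vector.
#' @param partition A [partition_windows()] result.
#' @return Integer window index per date (`NA` if outside every window).
#'   Windows are half-open, so a date on a boundary belongs to the later
#'   window.
#' @export
window_of <- function(dates, partition) {
  idx <- findInterval(as.integer(dates), as.integer(partition$start))
  idx[idx == 0] <- NA_integer_
  # findInterval places dates beyond the last start in the last window;
  # check the exclusive end
  last <- !is.na(idx) & idx == nrow(partition)
  idx[last & dates >= partition$end[nrow(partition)]] <- NA_integer_
  idx
}

# Internal: join assignments + records + window index; one row per
# assigned document that falls inside the partition.
cell_documents <- function(assignments, records, partition) {
  df <- dplyr::inner_join(
    dplyr::select(assignments, "doc_id", "topic_id"),
    dplyr::select(records, "doc_id", "pub_date"),
    by = "doc_id"
  )
  df$window_index <- window_of(df$pub_date, partition)
  df
}

all_cells <- function(topic_ids, partition) {
  tidyr::expand_grid(
    topic_id = sort(unique(topic_ids)),
    window_index = partition$window_index
  )
}

#' Research Effort Coverage per topic and window
#'
#' REC(t, w) is the fraction of the window's publications assigned to
#' topic t: the topic's share of research output in that window. The
#' denominator counts every in-window document (including unassigned
#' ones), so per-window RECs sum to 1 minus the unassigned share.
#'
#' @param assignments Tibble `doc_id`, `topic_id` (from
#'   [assign_documents()] or ground truth); `NA` topic = unassigned.
#' @param records Tibble with `doc_id`, `pub_date`.
#' @param partition A [partition_windows()] result.
#' @return Tibble `topic_id`, `window_index`, `n_docs`, `n_window`, `rec`;
#'   `rec` is `NA` for windows with no documents at all (flagged in the
#'   `"report"` attribute, along with documents outside the partition).
#' @export
compute_rec <- function(assignments, records, partition) {
  df <- cell_documents(assignments, records, partition)
  outside <- sum(is.na(df$window_index))
  df <- df[!is.na(df$window_index), , drop = FALSE]
  totals <- dplyr::count(df, .data$window_index, name = "n_window")
  cells <- dplyr::count(
    df[!is.na(df$topic_id), , drop = FALSE],
    .data$topic_id, .data$window_index, name = "n_docs"
  )
  grid <- all_cells(assignments$topic_id[!is.na(assignments$topic_id)],
                    partition)
  out <- grid |>
    dplyr::left_join(cells, by = c("topic_id", "window_index")) |>
    dplyr::left_join(totals, by = "window_index") |>
    dplyr::mutate(
      n_docs = dplyr::coalesce(.data$n_docs, 0L),
      n_window = dplyr::coalesce(.data$n_window, 0L),
      rec = ifelse(.data$n_window > 0, .data$n_docs / .data$n_window, NA_real_)
    )
  attr(out, "report") <- list(
    n_outside_partition = outside,
    empty_windows = setdiff(partition$window_index, totals$window_index)
  )
  out
}

#' Mann-Kendall monotone trend test
#'
#' Nonparametric trend test on an ordered series: `S` counts concordant
#' minus discordant pairs, its variance carries the standard tie
#' correction, and the normalized statistic uses a continuity correction
#' (`Z = (S - 1)/sqrt(Var)` for positive S, `(S + 1)/sqrt(Var)` for
#' negative). Missing values are dropped before testing.
#'
#' @param series Numeric vector in time order (`NA` allowed, dropped).
#' @param alpha Two-sided significance level (default 0.05, i.e. the
#'   standard 95% confidence level; significant iff `|Z| > z_{1-alpha/2}`).
#' @return Object of class `mk_trend`: list with `s_stat`, `var_s`,
#'   `z_mk`, `p_value`, `direction` (`"increasing"`, `"decreasing"`,
#'   `"none"` by the sign of S), `significant`, `n`, `too_short`.
#' @export
mann_kendall <- function(series, alpha = 0.05) {
  x <- series[!is.na(series)]
  n <- length(x)
  too_short <- n < 4
  if (n < 2) {
    return(structure(
      list(s_stat = NA_integer_, var_s = NA_real_, z_mk = NA_real_,
           p_value = NA_real_, direction = "none", significant = FALSE,
           n = n, too_short = TRUE, alpha = alpha),
      class = "mk_trend"))
  }
  pairs <- utils::combn(n, 2)
  s <- sum(sign(x[pairs[2, ]] - x[pairs[1, ]]))
  ties <- table(x)
  ties <- ties[ties > 1]
  var_s <- (n * (n - 1) * (2 * n + 5) -
              sum(ties * (ties - 1) * (2 * ties + 5))) / 18
  z <- if (var_s == 0) 0
       else if (s > 0) (s - 1) / sqrt(var_s)
       else if (s < 0) (s + 1) / sqrt(var_s)
       else 0
  p <- 2 * stats::pnorm(-abs(z))
  structure(
    list(s_stat = as.integer(s), var_s = var_s, z_mk = z, p_value = p,
         direction = if (s > 0) "increasing" else if (s < 0) "decreasing"
                     else "none",
         significant = !too_short && abs(z) > stats::qnorm(1 - alpha / 2),
         n = n, too_short = too_short, alpha = alpha),
    class = "mk_trend")
}

#' @exportS3Method base::print
print.mk_trend <- function(x, ...) {
  cat("<mk_trend> S = ", x$s_stat, ", Z = ", format(x$z_mk, digits = 4),
      ", ", x$direction,
      if (isTRUE(x$significant)) " (significant)" else " (not significant)",
      if (isTRUE(x$too_short)) " [series too short]" else "", "\n", sep = "")
  invisible(x)
}

#' @export
tidy.mk_trend <- function(x, ...) {
  tibble::tibble(
    s_stat = x$s_stat, var_s = x$var_s, z_mk = x$z_mk, p_value = x$p_value,
    direction = x$direction, significant = x$significant, n = x$n,
    too_short = x$too_short
  )
}

#' Research time distance per topic and window
#'
#' B(t, w) is the mean number of days between the outbreak starting point
#' and the publication dates of topic t's documents in window w. A
#' document published on the outbreak day itself is counted as 1 day
#' (keeping B positive so the response rate stays finite); a publication
#' date before the outbreak start violates the model and is an error.
#'
#' @inheritParams compute_rec
#' @param outbreak_start `Date` (or ISO string): the outbreak anchor.
#' @return Tibble `topic_id`, `window_index`, `b_days` (`NA` for empty
#'   cells).
#' @export
time_distance <- function(assignments, records, partition, outbreak_start) {
  outbreak_start <- parse_iso_date(outbreak_start)
  df <- cell_documents(assignments, records, partition)
  # the model precondition applies to every record, windowed or not
  if (any(records$pub_date < outbreak_start, na.rm = TRUE)) {
    stop("publication date(s) precede outbreak_start", call. = FALSE)
  }
  df <- df[!is.na(df$window_index) & !is.na(df$topic_id), , drop = FALSE]
  b <- as.integer(df$pub_date - outbreak_start)
  b[b == 0L] <- 1L
  df$b <- b
  cells <- df |>
    dplyr::group_by(.data$topic_id, .data$window_index) |>
    dplyr::summarise(b_days = mean(.data$b), .groups = "drop")
  all_cells(assignments$topic_id[!is.na(assignments$topic_id)], partition) |>
    dplyr::left_join(cells, by = c("topic_id", "window_index"))
}

#' Topic information entropy per topic and window
#'
#' Within each (topic, window) cell the global membership probabilities
#' `p(d|t)` of the cell's documents are renormalized to `q(d)` and the
#' Shannon entropy `-sum(q log q)` (natural log) is returned. High entropy
#' means the cell's mass is spread over many documents (a well-attested
#' cell); a cell with fewer than 2 documents has entropy 0 and is flagged,
#' since a one-document cell carries no membership uncertainty at all.
#'
#' @inheritParams compute_rec
#' @param probs Tibble `doc_id`, `topic_id`, `p`: global per-topic
#'   membership probabilities (from [doc_topic_probability()] or ground
#'   truth), summing to 1 within each topic.
#' @return Tibble `topic_id`, `window_index`, `n_docs`, `entropy`
#'   (`NA` for empty cells, 0 for singleton cells — see the
#'   `small_cell` flag column).
#' @export
topic_entropy <- function(probs, assignments, records, partition) {
  df <- cell_documents(assignments, records, partition)
  df <- df[!is.na(df$window_index) & !is.na(df$topic_id), , drop = FALSE]
  df <- dplyr::inner_join(df, probs, by = c("doc_id", "topic_id"))
  cells <- df |>
    dplyr::group_by(.data$topic_id, .data$window_index) |>
    dplyr::summarise(
      n_docs = dplyr::n(),
      entropy = {
        q <- .data$p / sum(.data$p)
        if (dplyr::n() < 2) 0 else -sum(q * log(q))
      },
      .groups = "drop"
    )
  all_cells(assignments$topic_id[!is.na(assignments$topic_id)], partition) |>
    dplyr::left_join(cells, by = c("topic_id", "window_index")) |>
    dplyr::mutate(
      n_docs = dplyr::coalesce(.data$n_docs, 0L),
      small_cell = .data$n_docs < 2
    )
}

#' Research Response Rate per topic and window
#'
#' RRR(t, w) divides the topic's probability mass published in the window
#' (the sum of global `p(d|t)` over the cell's documents) by the product
#' of research time distance and topic information entropy:
#' `RRR = sum(p) / (B * E)`. Fast, heavy, well-attested response gives a
#' large value; cells with entropy 0 (fewer than 2 documents) or no
#' documents yield `NA` and are flagged rather than returned as infinite.
#'
#' @inheritParams topic_entropy
#' @param b_table Result of [time_distance()].
#' @param e_table Result of [topic_entropy()].
#' @return Tibble `topic_id`, `window_index`, `mass`, `rrr`, `flag`.
#' @export
compute_rrr <- function(b_table, probs, e_table, assignments, records,
                        partition) {
  df <- cell_documents(assignments, records, partition)
  df <- df[!is.na(df$window_index) & !is.na(df$topic_id), , drop = FALSE]
  df <- dplyr::inner_join(df, probs, by = c("doc_id", "topic_id"))
  mass <- df |>
    dplyr::group_by(.data$topic_id, .data$window_index) |>
    dplyr::summarise(mass = sum(.data$p), .groups = "drop")
  out <- all_cells(assignments$topic_id[!is.na(assignments$topic_id)],
                   partition) |>
    dplyr::left_join(mass, by = c("topic_id", "window_index")) |>
    dplyr::left_join(
      dplyr::select(b_table, "topic_id", "window_index", "b_days"),
      by = c("topic_id", "window_index")) |>
    dplyr::left_join(
      dplyr::select(e_table, "topic_id", "window_index", "entropy"),
      by = c("topic_id", "window_index"))
  if (any(!is.na(out$b_days) & out$b_days == 0)) {
    stop("research time distance of 0 encountered", call. = FALSE)
  }
  out |>
    dplyr::mutate(
      rrr = dplyr::if_else(
        !is.na(.data$mass) & !is.na(.data$b_days) &
          !is.na(.data$entropy) & .data$entropy > 0,
        .data$mass / (.data$b_days * .data$entropy), NA_real_),
      flag = dplyr::case_when(
        is.na(.data$mass) ~ "empty_cell",
        is.na(.data$entropy) | .data$entropy == 0 ~ "small_cell",
        TRUE ~ ""
      )
    ) |>
    dplyr::select("topic_id", "window_index", "mass", "rrr", "flag")
}

#' Full Research Priority Metric table
#'
#' Convenience wrapper computing REC, research time distance, topic
#' entropy and RRR in one tidy table, one row per (topic, window).
#'
#' @inheritParams topic_entropy
#' @param outbreak_start `Date` (or ISO string) anchoring the time
#'   distance.
#' @return Tibble of class `rpm_table` with columns `topic_id`,
#'   `window_index`, `window_start`, `n_docs`, `n_window`, `rec`,
#'   `b_days`, `entropy`, `rrr`, `flag`.
#' @export
rpm_table <- function(assignments, probs, records, partition,
                      outbreak_start) {
  rec <- compute_rec(assignments, records, partition)
  b <- time_distance(assignments, records, partition, outbreak_start)
  e <- topic_entropy(probs, assignments, records, partition)
  r <- compute_rrr(b, probs, e, assignments, records, partition)
  out <- rec |>
    dplyr::left_join(b, by = c("topic_id", "window_index")) |>
    dplyr::left_join(
      dplyr::select(e, "topic_id", "window_index", "entropy"),
      by = c("topic_id", "window_index")) |>
    dplyr::left_join(
      dplyr::select(r, "topic_id", "window_index", "mass", "rrr", "flag"),
      by = c("topic_id", "window_index")) |>
    dplyr::left_join(
      dplyr::select(partition, "window_index", window_start = "start"),
      by = "window_index") |>
    dplyr::select("topic_id", "window_index", "window_start", "n_docs",
                  "n_window", "rec", "b_days", "entropy", "mass", "rrr",
                  "flag")
  attr(out, "report") <- attr(rec, "report")
  class(out) <- c("rpm_table", class(out))
  out
}

#' Write an RPM table as tidy CSV
#'
#' @param x An [rpm_table()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_rpm_table <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE, na = "")
  invisible(path)
}
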