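#' Classify a hotspot's temporal type from its RRR trajectory
#'
#' Operationalizes the three temporal archetypes a reader would assign by
#' inspection of an RRR trajectory:
#' \describe{
#'   \item{fluctuating}{large swings: at least `min_sign_changes` sign
#'     changes among the material first differences, or detrended
#'     coefficient of variation of at least `theta_cv`;}
#'   \item{emergency}{response peaks in the first window and decays;}
#'   \item{persistent}{response peaks in the second window, then declines
#'     slowly.}
#' }
#' Rules are applied in that order; if the peak is later than window 2 the
#' fallback labels the series persistent when its Mann-Kendall trend is
#' non-increasing and fluctuating otherwise. Missing windows are skipped.
#'
#' Two robustness choices, both configurable: the CV is computed on
#' residuals from a linear trend fit (a raw CV cannot separate a decaying
#' emergency trajectory from genuine fluctuation — any series that falls
#' several-fold has raw CV near or above the threshold); and a first
#' difference only counts toward sign changes when its magnitude exceeds
#' `amp_frac * sd(series)`, so counting noise in a flat tail does not
#' register as fluctuation.
#'
#' @param rrr_series Numeric RRR values in window order (`NA` allowed).
#' @param theta_cv Detrended-CV threshold for the fluctuating rule.
#' @param min_sign_changes Sign-change count threshold.
#' @param amp_frac Fraction of `sd(series)` a first difference must exceed
#'   to count as a direction change.
#' @param alpha Significance level for the fallback trend test.
#' @return List with `type` (`"emergency"`, `"persistent"`,
#'   `"fluctuating"`, or `"unclassified"` when fewer than 4 values are
#'   available) and `evidence` (peak window, detrended CV, material sign
#'   changes, Mann-Kendall Z of the series).
#' @export
classify_type <- function(rrr_series, theta_cv = 0.5, min_sign_changes = 3,
                          amp_frac = 0.25, alpha = 0.05) {
  idx <- which(!is.na(rrr_series))
  x <- rrr_series[idx]
  if (length(x) < 4) {
    return(list(type = "unclassified",
                evidence = list(rrr_peak_window = NA_integer_,
                                rrr_cv = NA_real_, sign_changes = NA_integer_,
                                rrr_mk_z = NA_real_)))
  }
  peak_window <- idx[which.max(x)]
  # detrended CV: sd of residuals from a linear fit, relative to the mean
  fit <- stats::lm.fit(cbind(1, seq_along(x)), x)
  rcv <- stats::sd(fit$residuals) / abs(mean(x))
  # sign changes among material first differences
  d <- diff(x)
  d <- d[abs(d) > amp_frac * stats::sd(x)]
  sgn <- sign(d)
  sgn <- sgn[sgn != 0]
  n_changes <- if (length(sgn) < 2) 0L else sum(diff(sgn) != 0)
  mk <- mann_kendall(x, alpha = alpha)

  type <- if (n_changes >= min_sign_changes || rcv >= theta_cv) {
    "fluctuating"
  } else if (peak_window == 1L) {
    "emergency"
  } else if (peak_window == 2L) {
    "persistent"
  } else if (mk$s_stat <= 0) {
    "persistent"
  } else {
    "fluctuating"
  }
  list(type = type,
       evidence = list(rrr_peak_window = peak_window, rrr_cv = rcv,
                       sign_changes = n_changes, rrr_mk_z = mk$z_mk))
}

#' Map a temporal type and an REC trend to a priority region
#'
#' Regions form a 3 x 3 grid: the letter is the type initial (E/P/F) and
#' the digit encodes the REC trend — 1 for a significant decrease, 3 for a
#' significant increase, 2 otherwise (stable). An unclassified type maps
#' to letter "U".
#'
#' @param type_label `"emergency"`, `"persistent"`, `"fluctuating"`, or
#'   `"unclassified"`.
#' @param rec_trend An `mk_trend` from [mann_kendall()] on the topic's REC
#'   series.
#' @return Region string such as `"E-1"` or `"P-3"`.
#' @export
classify_region <- function(type_label, rec_trend) {
  stopifnot(inherits(rec_trend, "mk_trend"))
  letter <- switch(type_label,
    emergency = "E", persistent = "P", fluctuating = "F", "U")
  digit <- if (isTRUE(rec_trend$significant)) {
    if (rec_trend$direction == "decreasing") "1" else "3"
  } else "2"
  paste0(letter, "-", digit)
}

#' Classify every topic's type, REC trend and priority region
#'
#' Applies [classify_type()] to each topic's RRR trajectory and
#' [mann_kendall()] to its REC trajectory, then maps the pair to a
#' priority region with [classify_region()].
#'
#' @param rpm An [rpm_table()] result.
#' @param alpha Significance level for the REC trend test.
#' @param ... Passed to [classify_type()].
#' @return Tibble of class `priority_result`: one row per topic with
#'   `topic_id`, `type`, `rec_trend` (direction), `rec_significant`,
#'   `trend_symbol` (`+`/`-`/`o`, with `**` appended when significant at
#'   `alpha`), `region`, and evidence columns `rrr_peak_window`, `rrr_cv`,
#'   `rrr_mk_z`, `rec_mk_z`.
#' @export
classify_priorities <- function(rpm, alpha = 0.05, ...) {
  out <- rpm |>
    dplyr::arrange(.data$topic_id, .data$window_index) |>
    dplyr::group_by(.data$topic_id) |>
    dplyr::group_modify(function(g, key) {
      ct <- classify_type(g$rrr, alpha = alpha, ...)
      mk <- mann_kendall(g$rec, alpha = alpha)
      symbol <- if (!isTRUE(mk$significant)) "o"
                else if (mk$direction == "increasing") "+"
                else "-"
      tibble::tibble(
        type = ct$type,
        rec_trend = if (isTRUE(mk$significant)) mk$direction else "stable",
        rec_significant = isTRUE(mk$significant),
        trend_symbol = paste0(symbol,
                              if (isTRUE(mk$significant)) "**" else ""),
        region = classify_region(ct$type, mk),
        rrr_peak_window = ct$evidence$rrr_peak_window,
        rrr_cv = ct$evidence$rrr_cv,
        rrr_mk_z = ct$evidence$rrr_mk_z,
        rec_mk_z = mk$z_mk
      )
    }) |>
    dplyr::ungroup()
  class(out) <- c("priority_result", class(out))
  out
}

#' Summary report of priorities with hotspot keywords
#'
#' Joins the classification with each hotspot's top keywords into the
#' deterministic summary table users publish (topic, keywords, type,
#' trend symbol with significance stars, region).
#'
#' @param results A [classify_priorities()] result.
#' @param hotspots A [top_terms()] tibble (any depth).
#' @return Tibble with one row per topic: `topic_id`, `keywords`
#'   (comma-separated), `type`, `trend_symbol`, `region`.
#' @export
priority_report <- function(results, hotspots) {
  kw <- hotspots |>
    dplyr::arrange(.data$topic_id, .data$rank) |>
    dplyr::group_by(.data$topic_id) |>
    dplyr::summarise(keywords = paste(.data$lemma, collapse = ", "),
                     .groups = "drop")
  results |>
    dplyr::left_join(kw, by = "topic_id") |>
    dplyr::select("topic_id", "keywords", "type", "trend_symbol", "region")
}

#' Write a priority report as CSV
#'
#' @param x A [priority_report()] tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_priority_report <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
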