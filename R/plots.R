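#' Plot the topic-number diagnostics
#'
#' Stability (higher is better) and divergence (lower is better) against
#' the candidate number of topics, with the selected k marked.
#'
#' @param object A `k_selection` from [select_k()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.k_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("k", "stability", "divergence")],
    cols = c("stability", "divergence"),
    names_to = "diagnostic", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_vline(xintercept = attr(object, "k_selected"),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~diagnostic, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "number of topics k", y = NULL,
                  title = "Topic-number selection diagnostics") +
    ggplot2::theme_minimal()
}

#' Plot per-topic metric trajectories across time-windows
#'
#' @param object An `rpm_table` from [rpm_table()].
#' @param metric `"rec"`, `"rrr"`, `"b_days"` or `"entropy"`.
#' @param ... Unused.
#' @return A ggplot object: one line per topic over window index.
#' @export
autoplot.rpm_table <- function(object, metric = c("rec", "rrr", "b_days",
                                                  "entropy"), ...) {
  metric <- match.arg(metric)
  df <- tibble::as_tibble(object)
  df$topic <- factor(paste0("T", df$topic_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$window_index,
                                   y = .data[[metric]],
                                   colour = .data$topic)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(size = 1, na.rm = TRUE) +
    ggplot2::scale_x_continuous(breaks = unique(df$window_index)) +
    ggplot2::labs(x = "time-window", y = toupper(metric), colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the priority-region grid
#'
#' Places each topic in the 3 x 3 grid of temporal type (rows) against
#' REC trend (columns), the summary view of the classification.
#'
#' @param object A `priority_result` from [classify_priorities()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.priority_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$type <- factor(df$type,
                    levels = c("fluctuating", "persistent", "emergency"))
  df$trend <- factor(df$rec_trend,
                     levels = c("decreasing", "stable", "increasing"))
  df$label <- paste0("T", df$topic_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trend, y = .data$type)) +
    ggplot2::geom_tile(fill = NA, colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       position = ggplot2::position_jitter(width = 0.25,
                                                           height = 0.25,
                                                           seed = 1)) +
    ggplot2::labs(x = "REC trend", y = "temporal type",
                  title = "Priority regions") +
    ggplot2::theme_minimal()
}
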