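# ggplot2 views of the analysis results.

#' Bar chart of per-group activity frequency shares
#'
#' @param freqs Output of [activity_frequencies()].
#' @return A ggplot object: activity share per code, faceted bars per group.
#' @export
plot_activity_frequencies <- function(freqs) {
  freqs |>
    dplyr::mutate(code = factor(.data$code, levels = rev(.activity_codes))) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$code, y = 100 * .data$share, fill = .data$stage
    )) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(ggplot2::vars(.data$group)) +
    ggplot2::labs(x = NULL, y = "share of group activities (%)",
                  fill = "stage") +
    ggplot2::theme_minimal()
}

#' Heatmap of a transition matrix
#'
#' @param object A `transition_matrix`.
#' @param what `"p"` for row-conditional probabilities (default) or `"n"`
#'   for counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.transition_matrix <- function(object, what = c("p", "n"), ...) {
  what <- match.arg(what)
  tidy.transition_matrix(object) |>
    dplyr::mutate(
      from = factor(.data$from, levels = rev(object$state_order)),
      to = factor(.data$to, levels = object$state_order)
    ) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$to, y = .data$from,
                                 fill = .data[[what]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "to", y = "from",
      fill = if (what == "p") "P(to | from)" else "count"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, hjust = 1))
}

#' Perplexity curve over n-gram orders
#'
#' @param object An `order_selection`.
#' @param ... Unused.
#' @return A ggplot object with the selected order marked.
#' @export
autoplot.order_selection <- function(object, ...) {
  ggplot2::ggplot(object$results,
                  ggplot2::aes(x = .data$order, y = .data$perplexity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$best_order, linetype = "dashed") +
    ggplot2::scale_x_continuous(breaks = object$results$order) +
    ggplot2::labs(x = "n-gram order", y = "held-out perplexity") +
    ggplot2::theme_minimal()
}

#' Category share comparison across familiarity groups
#'
#' @param object A `pattern_summary`.
#' @param ... Unused.
#' @return A ggplot object: summed top-k window share per behavioural
#'   category and group.
#' @export
autoplot.pattern_summary <- function(object, ...) {
  ggplot2::ggplot(object$categories,
                  ggplot2::aes(x = factor(.data$category),
                               y = .data$share_pct, fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "behavioural category",
                  y = "share of group windows in top-k patterns (%)",
                  fill = "group") +
    ggplot2::theme_minimal()
}
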