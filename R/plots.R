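#' Plot the screening funnel
#'
#' Bar chart of the funnel counts (common -> hub-like -> core -> critical).
#'
#' @param object A [run_screen()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.screen_result <- function(object, ...) {
  dat <- object$funnel |>
    mutate(stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$stage, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), vjust = -0.4) +
    ggplot2::labs(x = "screening stage", y = "proteins",
                  title = "Cross-disease screening funnel") +
    ggplot2::theme_minimal()
}

#' Plot a network's degree distribution
#'
#' Log-log scatter of the complementary degree rank against degree; a
#' roughly linear tail indicates the heavy-tailed (scale-free-like)
#' structure hub screening assumes.
#'
#' @param object A [ppi_network()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ppi_network <- function(object, ...) {
  deg <- sort(lengths(adjacency_list(object)), decreasing = TRUE)
  dat <- tibble(rank = seq_along(deg), degree = deg) |>
    filter(.data$degree > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$degree, y = .data$rank)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "rank (descending)",
                  title = sprintf("Degree distribution: %s", object$disease_id)) +
    ggplot2::theme_minimal()
}
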