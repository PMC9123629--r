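#' Tidy a screen result into funnel counts
#'
#' @param x A [run_screen()] result.
#' @param ... Unused.
#' @return A tibble with columns `stage` (`common`, `hublike`, `core`,
#'   `critical`) and `count`.
#' @export
tidy.screen_result <- function(x, ...) {
  x$funnel
}

#' One-row summary of a screen result
#'
#' @param x A [run_screen()] result.
#' @param ... Unused.
#' @return A one-row tibble: number of networks, funnel counts, hub count
#'   and whether the action screen ran.
#' @export
glance.screen_result <- function(x, ...) {
  tibble(
    n_networks = length(x$centrality),
    n_common = length(x$common_set),
    n_hublike = length(x$hublike_common),
    n_core = length(x$action_core),
    n_hubs = length(x$common_hubs),
    n_critical = length(x$critical_set),
    action_screened = x$action_screened
  )
}

#' Edge table of a network
#'
#' @param x A [ppi_network()].
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`).
#' @export
tidy.ppi_network <- function(x, ...) {
  x$edges
}

#' One-row topology summary of a network
#'
#' @param x A [ppi_network()].
#' @param ... Unused.
#' @return A one-row tibble: disease id, node and edge counts, density, and
#'   maximum/median degree.
#' @export
glance.ppi_network <- function(x, ...) {
  deg <- lengths(adjacency_list(x))
  n <- length(x$nodes)
  tibble(
    disease_id = x$disease_id,
    n_nodes = n,
    n_edges = nrow(x$edges),
    density = if (n >= 2) nrow(x$edges) / (n * (n - 1) / 2) else NA_real_,
    max_degree = if (n > 0) max(deg) else NA_integer_,
    median_degree = if (n > 0) stats::median(deg) else NA_real_
  )
}
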