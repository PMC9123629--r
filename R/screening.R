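#' Select the top degree percentile of a network's nodes
#'
#' Ranks a centrality table by degree (descending, ties broken by node label
#' ascending) and returns the top `percentile` percent. The cut size is
#' `max(1, round(percentile / 100 * n))`, so at least one node is always
#' selected. In `"strict"` mode exactly `cut_size` nodes are returned, the
#' boundary tie resolved lexicographically; `"include_ties"` additionally
#' keeps every node whose degree equals that of the last strictly included
#' node.
#'
#' @param records A centrality tibble (see [centrality_table()]); non-empty.
#' @param percentile Percentage in `(0, 100]`. 10 selects hubs, 50 the
#'   relaxed hub-like set.
#' @param tie_policy `"strict"` (default) or `"include_ties"`.
#' @return A tibble of the selected rows (same columns as `records`), in rank
#'   order, with attributes `percentile`, `cut_size` and (when present on
#'   `records`) `disease_id`.
#' @examples
#' tbl <- tibble::tibble(node = c("A", "B", "C"), degree = c(5L, 5L, 1L))
#' top_percent(tbl, 34)$node
#' top_percent(tbl, 34, tie_policy = "include_ties")$node
#' @export
top_percent <- function(records, percentile,
                        tie_policy = c("strict", "include_ties")) {
  tie_policy <- match.arg(tie_policy)
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort_validation("`records` must be a non-empty centrality table.")
  }
  if (!is.numeric(percentile) || length(percentile) != 1L ||
      is.na(percentile) || percentile <= 0 || percentile > 100) {
    abort_validation("`percentile` must be a single number in (0, 100].")
  }
  ranked <- arrange(records, desc(.data$degree), .data$node)
  n <- nrow(ranked)
  cut_size <- max(1L, as.integer(round(percentile / 100 * n)))
  cut_size <- min(cut_size, n)
  sel <- ranked[seq_len(cut_size), ]
  if (tie_policy == "include_ties") {
    boundary <- sel$degree[cut_size]
    sel <- ranked[seq_len(n) <= cut_size | ranked$degree == boundary, ]
  }
  attr(sel, "percentile") <- percentile
  attr(sel, "cut_size") <- cut_size
  attr(sel, "disease_id") <- attr(records, "disease_id", exact = TRUE)
  sel
}

#' Proteins shared by every disease network
#'
#' Intersects the node sets of two or more disease networks. The result is
#' independent of network order.
#'
#' @param networks A list of at least two [ppi_network()] objects.
#' @return A sorted character vector of shared protein symbols, with the
#'   contributing `disease_id`s attached as attribute `diseases`.
#' @export
common_proteins <- function(networks) {
  if (!is.list(networks) || length(networks) < 2L) {
    abort_validation("`networks` must be a list of at least two networks.")
  }
  walk(networks, function(x) {
    if (!inherits(x, "ppi_network")) {
      abort_validation("Every element of `networks` must be a `ppi_network`.")
    }
  })
  members <- sort(reduce(map(networks, "nodes"), intersect))
  attr(members, "diseases") <- map_chr(networks, "disease_id")
  members
}

# Shared machinery: members of `common` inside the top-`percentile` set of
# every network ("all") or of at least one ("any").
common_in_top <- function(tables, common, percentile, tie_policy, scope) {
  if (!is.list(tables) || length(tables) < 2L) {
    abort_validation("`tables` must be a list of at least two centrality tables.")
  }
  tops <- map(tables, function(tbl) {
    top_percent(tbl, percentile, tie_policy = tie_policy)$node
  })
  pool <- switch(scope, all = reduce(tops, intersect), any = reduce(tops, union))
  sort(intersect(as.character(common), pool))
}

#' Shared hub-like proteins (top 50% by degree everywhere)
#'
#' From a cross-disease common protein set, keeps the members that fall in
#' the top `percentile` percent by degree of every analysed network (the
#' relaxed "hub-like" screen preceding action-map analysis).
#'
#' @param tables A named list of per-disease centrality tibbles, one per
#'   network used to compute `common`.
#' @param common Character vector of shared proteins, from
#'   [common_proteins()].
#' @param percentile Degree percentile; defaults to 50 for the hub-like
#'   screen.
#' @param tie_policy Passed to [top_percent()].
#' @param scope `"all"` (default) requires top-percentile membership in every
#'   network; `"any"` accepts membership in at least one.
#' @return Sorted character vector of hub-like shared proteins.
#' @export
common_hublike <- function(tables, common, percentile = 50,
                           tie_policy = "strict", scope = c("all", "any")) {
  scope <- match.arg(scope)
  common_in_top(tables, common, percentile, tie_policy, scope)
}

#' Shared hub proteins (top 10% by degree everywhere)
#'
#' The strict hub version of [common_hublike()]: members of the common set
#' ranked in the top `percentile` (default 10) percent by degree of every
#' network — for 100-node networks, the ten top individuals of each.
#'
#' @inheritParams common_hublike
#' @param percentile Degree percentile; defaults to 10 for hub selection.
#' @return Sorted character vector of common hub (central node) proteins.
#' @export
common_hubs <- function(tables, common, percentile = 10,
                        tie_policy = "strict", scope = c("all", "any")) {
  scope <- match.arg(scope)
  common_in_top(tables, common, percentile, tie_policy, scope)
}
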