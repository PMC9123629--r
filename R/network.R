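#' Construct a disease interaction network
#'
#' A `ppi_network` is a simple undirected labelled graph: a set of protein
#' symbols (case-sensitive, never remapped) and a set of unordered edges
#' between them. Self-loops are dropped with a warning and parallel edges are
#' collapsed, so node degree has the usual simple-graph meaning.
#'
#' @param edges A data frame whose first two columns give the endpoints of
#'   each interaction (character). Extra columns (e.g. a confidence score)
#'   are ignored for topology.
#' @param nodes Optional character vector of node labels; the final node set
#'   is the union of `nodes` and all edge endpoints, so isolated proteins can
#'   be represented.
#' @param disease_id Short label for the disease or condition the network
#'   describes.
#' @param quiet If `TRUE`, suppress the self-loop warning.
#'
#' @return An object of class `ppi_network` with elements `disease_id`,
#'   `nodes` (sorted character vector) and `edges` (a tibble with columns
#'   `from` and `to`, canonically ordered so `from < to` and sorted).
#' @examples
#' net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")), disease_id = "demo")
#' net
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, disease_id = "network",
                        quiet = FALSE) {
  check_string(disease_id, "disease_id")
  if (is.null(edges)) {
    edges <- tibble(from = character(), to = character())
  }
  if (!is.data.frame(edges) || ncol(edges) < 2L) {
    abort_validation("`edges` must be a data frame with at least two columns.")
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  if (anyNA(a) || anyNA(b) || any(!nzchar(a)) || any(!nzchar(b))) {
    abort_validation("Edge endpoints must be non-empty protein symbols.")
  }
  loops <- a == b
  if (any(loops)) {
    if (!quiet) {
      warn(sprintf("Dropped %d self-loop edge(s).", sum(loops)),
           class = "hubscreen_warning")
    }
    a <- a[!loops]
    b <- b[!loops]
  }
  edge_tbl <- tibble(from = pmin(a, b), to = pmax(a, b)) |>
    distinct() |>
    arrange(.data$from, .data$to)
  all_nodes <- sort(unique(c(as.character(nodes %||% character()),
                             edge_tbl$from, edge_tbl$to)))
  if (anyNA(all_nodes) || any(!nzchar(all_nodes))) {
    abort_validation("Node labels must be non-empty strings.")
  }
  structure(
    list(disease_id = disease_id, nodes = all_nodes, edges = edge_tbl),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %s: %d nodes, %d edges\n",
              x$disease_id, length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' @export
as_tibble.ppi_network <- function(x, ...) x$edges

#' Number of nodes / edges in a network
#' @param net A [ppi_network()].
#' @return An integer count.
#' @export
n_nodes <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  length(net$nodes)
}

#' @rdname n_nodes
#' @export
n_edges <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  nrow(net$edges)
}

# Neighbour lists as integer indices into net$nodes, every node present
# (isolated nodes get an empty vector). Deterministically sorted.
adjacency_list <- function(net) {
  n <- length(net$nodes)
  if (n == 0L) return(list())
  i <- match(net$edges$from, net$nodes)
  j <- match(net$edges$to, net$nodes)
  adj <- split(c(j, i), factor(c(i, j), levels = seq_len(n)))
  adj <- lapply(adj, function(x) sort(as.integer(x)))
  names(adj) <- NULL
  adj
}
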