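#' Node centralities of a disease network
#'
#' Computes the four topological centrality parameters used for hub screening:
#'
#' * **degree** (K): number of distinct direct neighbours;
#' * **betweenness** (BC): fraction of shortest paths passing through the
#'   node, normalised to `[0, 1]` by `2 / ((n - 1)(n - 2))` with `n` the total
#'   node count of the graph (not the component size), unordered endpoint
#'   pairs counted once;
#' * **closeness** (CC): number of nodes reachable from the node divided by
#'   the sum of shortest-path distances to them (0 for an isolated node), so
#'   disconnected graphs stay finite;
#' * **stress**: raw integer count of shortest paths, over unordered
#'   endpoint pairs, that contain the node as an interior vertex.
#'
#' All shortest paths are unweighted (hop counts). Betweenness and stress are
#' accumulated with a Brandes-style single-source scheme, O(n m) overall.
#'
#' @param net A [ppi_network()].
#' @return `centrality_table()` returns a tibble with columns `node`,
#'   `degree`, `betweenness`, `closeness`, `stress`, one row per node, sorted
#'   by degree descending then node label ascending, with the network's
#'   `disease_id` attached as an attribute. The single-metric helpers return
#'   a two-column tibble (`node` plus the metric) in the same order.
#' @examples
#' star <- ppi_network(data.frame(a = "hub", b = paste0("leaf", 1:4)))
#' centrality_table(star)
#' @export
centrality_table <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- length(net$nodes)
  if (n == 0L) {
    out <- tibble(node = character(), degree = integer(),
                  betweenness = double(), closeness = double(),
                  stress = double())
    attr(out, "disease_id") <- net$disease_id
    return(out)
  }
  adj <- adjacency_list(net)
  acc <- brandes_accumulate(adj)
  bet <- if (n >= 3L) acc$betweenness_ordered / ((n - 1) * (n - 2)) else
    rep(0, n)
  out <- tibble(
    node = net$nodes,
    degree = lengths(adj),
    betweenness = bet,
    closeness = acc$closeness,
    stress = acc$stress_ordered / 2
  ) |>
    arrange(desc(.data$degree), .data$node)
  attr(out, "disease_id") <- net$disease_id
  out
}

#' @rdname centrality_table
#' @export
node_degree <- function(net) {
  centrality_table(net) |> select("node", "degree")
}

#' @rdname centrality_table
#' @export
node_betweenness <- function(net) {
  centrality_table(net) |> select("node", "betweenness")
}

#' @rdname centrality_table
#' @export
node_closeness <- function(net) {
  centrality_table(net) |> select("node", "closeness")
}

#' @rdname centrality_table
#' @export
node_stress <- function(net) {
  centrality_table(net) |> select("node", "stress")
}

# One BFS per source; accumulates, over ordered (s, v) contributions:
#   - betweenness dependencies (Brandes' delta),
#   - stress counts sigma_sv * (# DAG paths from v), and
#   - closeness from the distance vector.
# Ordered sums count each unordered pair twice; callers halve them.
brandes_accumulate <- function(adj) {
  n <- length(adj)
  bet <- numeric(n)
  stress <- numeric(n)
  closeness <- numeric(n)
  queue <- integer(n)
  for (s in seq_len(n)) {
    dist <- rep.int(-1L, n)
    sigma <- numeric(n)
    preds <- vector("list", n)
    dist[s] <- 0L
    sigma[s] <- 1
    queue[1L] <- s
    qlen <- 1L
    ptr <- 1L
    while (ptr <= qlen) {
      v <- queue[ptr]
      ptr <- ptr + 1L
      dv1 <- dist[v] + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dv1
          qlen <- qlen + 1L
          queue[qlen] <- w
        }
        if (dist[w] == dv1) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    reach <- qlen - 1L
    if (reach > 0L) {
      closeness[s] <- reach / sum(dist[queue[seq_len(qlen)]])
    }
    delta <- numeric(n)
    npaths <- numeric(n) # DAG paths from v to any descendant
    for (k in seq.int(qlen, 1L)) {
      v <- queue[k]
      for (p in preds[[v]]) {
        delta[p] <- delta[p] + sigma[p] / sigma[v] * (1 + delta[v])
        npaths[p] <- npaths[p] + 1 + npaths[v]
      }
      if (v != s) {
        bet[v] <- bet[v] + delta[v]
        stress[v] <- stress[v] + sigma[v] * npaths[v]
      }
    }
  }
  list(betweenness_ordered = bet, stress_ordered = stress,
       closeness = closeness)
}
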