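# Brute-force centrality oracle: enumerates every shortest path explicitly
# with igraph::all_shortest_paths and counts per the package's declared
# conventions. Deliberately independent of the Brandes accumulation in R/.

oracle_centrality <- function(net) {
  n <- length(net$nodes)
  g <- igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = data.frame(name = net$nodes)
  )
  dmat <- igraph::distances(g)
  deg <- igraph::degree(g)

  bet_raw <- stats::setNames(numeric(n), net$nodes)
  stress <- stats::setNames(numeric(n), net$nodes)
  if (n >= 2) {
    for (si in seq_len(n - 1)) {
      for (ti in seq.int(si + 1, n)) {
        if (!is.finite(dmat[si, ti])) next
        paths <- igraph::all_shortest_paths(g, from = si, to = ti)$vpaths
        sigma <- length(paths)
        interior <- lapply(paths, function(p) {
          nm <- names(p)
          if (length(nm) > 2) nm[-c(1, length(nm))] else character()
        })
        hits <- table(unlist(interior))
        if (length(hits) > 0) {
          bet_raw[names(hits)] <- bet_raw[names(hits)] + hits / sigma
          stress[names(hits)] <- stress[names(hits)] + hits
        }
      }
    }
  }
  betweenness <- if (n >= 3) bet_raw * 2 / ((n - 1) * (n - 2)) else bet_raw * 0

  closeness <- vapply(seq_len(n), function(i) {
    d <- dmat[i, -i]
    d <- d[is.finite(d)]
    if (length(d) == 0) 0 else length(d) / sum(d)
  }, numeric(1))

  tibble::tibble(
    node = net$nodes,
    degree = as.integer(deg[net$nodes]),
    betweenness = unname(betweenness[net$nodes]),
    closeness = closeness,
    stress = unname(stress[net$nodes])
  )
}

# Seeded Erdos-Renyi style random networks, occasionally with an extra
# isolated node, for oracle-equivalence checks.
random_network <- function(n, p, seed, isolated = FALSE) {
  withr::with_seed(seed, {
    labels <- sprintf("P%02d", seq_len(n))
    pairs <- utils::combn(labels, 2)
    keep <- stats::runif(ncol(pairs)) < p
    edges <- data.frame(from = pairs[1, keep], to = pairs[2, keep])
    nodes <- if (isolated) c(labels, "LONER") else labels
    ppi_network(edges, nodes = nodes, disease_id = sprintf("rand%d", seed))
  })
}

expect_centrality_equal <- function(got, want, tol = 1e-9) {
  got <- dplyr::arrange(got, node)
  want <- dplyr::arrange(want, node)
  expect_identical(got$node, want$node)
  expect_identical(got$degree, want$degree)
  expect_equal(got$stress, want$stress, tolerance = 0)
  expect_true(max(abs(got$betweenness - want$betweenness)) <= tol)
  expect_true(max(abs(got$closeness - want$closeness)) <= tol)
}
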