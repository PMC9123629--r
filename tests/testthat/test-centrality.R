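make_star <- function(k = 4) {
  ppi_network(data.frame(a = "center", b = paste0("leaf", seq_len(k))))
}

test_that("star graph matches analytic centralities", {
  tbl <- centrality_table(make_star(4))
  center <- tbl[tbl$node == "center", ]
  leaves <- tbl[tbl$node != "center", ]
  expect_identical(center$degree, 4L)
  expect_equal(center$betweenness, 1)
  expect_equal(center$closeness, 1)
  expect_equal(center$stress, choose(4, 2))
  expect_true(all(leaves$degree == 1L))
  expect_true(all(leaves$betweenness == 0))
  expect_equal(leaves$closeness, rep(4 / (1 + 2 * 3), 4))
  expect_true(all(leaves$stress == 0))
})

test_that("path graph A-B-C matches analytic centralities", {
  net <- ppi_network(data.frame(a = c("A", "B"), b = c("B", "C")))
  tbl <- centrality_table(net)
  b <- tbl[tbl$node == "B", ]
  expect_equal(b$betweenness, 1)
  expect_equal(b$stress, 1)
  a <- tbl[tbl$node == "A", ]
  expect_equal(a$closeness, 2 / 3)
  expect_equal(a$betweenness, 0)
})

test_that("triangle and complete graphs have uniform trivial centralities", {
  tri <- ppi_network(data.frame(a = c("A", "B", "C"), b = c("B", "C", "A")))
  tbl <- centrality_table(tri)
  expect_true(all(tbl$degree == 2L))
  expect_true(all(tbl$betweenness == 0))
  expect_true(all(tbl$closeness == 1))
  expect_true(all(tbl$stress == 0))

  labels <- paste0("K", 1:6)
  pairs <- utils::combn(labels, 2)
  k6 <- ppi_network(data.frame(a = pairs[1, ], b = pairs[2, ]))
  tbl6 <- centrality_table(k6)
  expect_true(all(tbl6$betweenness == 0))
  expect_true(all(tbl6$closeness == 1))
  expect_true(all(tbl6$degree == 5L))
})

test_that("cycle symmetry: all nodes of C_n share identical values", {
  labels <- paste0("N", 1:7)
  net <- ppi_network(data.frame(a = labels, b = labels[c(2:7, 1)]))
  tbl <- centrality_table(net)
  for (col in c("degree", "betweenness", "closeness", "stress")) {
    expect_length(unique(tbl[[col]]), 1L)
  }
})

test_that("degree obeys the handshake identity on generated networks", {
  net <- generate_network(scenario_config(seed = 9L), 1L)
  deg <- node_degree(net)
  expect_identical(sum(deg$degree), 2L * n_edges(net))
})

test_that("disconnected graphs stay finite and in range; isolated nodes are zero", {
  net <- ppi_network(
    data.frame(a = c("A", "B", "X"), b = c("B", "C", "Y")),
    nodes = c("LONE")
  )
  tbl <- centrality_table(net)
  expect_true(all(is.finite(tbl$betweenness)))
  expect_true(all(tbl$betweenness >= 0 & tbl$betweenness <= 1))
  expect_true(all(tbl$closeness >= 0 & tbl$closeness <= 1))
  expect_true(all(tbl$stress >= 0))
  lone <- tbl[tbl$node == "LONE", ]
  expect_identical(unname(unlist(lone[, -1])), rep(0, 4))
})

test_that("graphs with fewer than three nodes have zero betweenness", {
  pair <- ppi_network(data.frame(a = "A", b = "B"))
  expect_true(all(node_betweenness(pair)$betweenness == 0))
  expect_identical(nrow(centrality_table(ppi_network())), 0L)
})

test_that("centralities match the path-enumeration oracle on random graphs", {
  # small ensemble here; the full 50-graph sweep runs in the acceptance suite
  for (seed in 1:8) {
    net <- random_network(n = 12 + seed %% 5, p = 0.25, seed = seed,
                          isolated = seed %% 3 == 0)
    expect_centrality_equal(centrality_table(net), oracle_centrality(net))
  }
})

test_that("single-metric helpers agree with the combined table", {
  net <- generate_network(scenario_config(seed = 21L), 2L)
  tbl <- centrality_table(net)
  expect_identical(node_degree(net), dplyr::select(tbl, node, degree))
  expect_identical(node_betweenness(net), dplyr::select(tbl, node, betweenness))
  expect_identical(node_closeness(net), dplyr::select(tbl, node, closeness))
  expect_identical(node_stress(net), dplyr::select(tbl, node, stress))
  # deterministic output order: degree desc, label asc
  expect_false(is.unsorted(rev(tbl$degree)))
  expect_identical(attr(tbl, "disease_id"), net$disease_id)
})

test_that("adding an edge never decreases any degree", {
  base <- random_network(10, 0.2, 33)
  deg0 <- node_degree(base)
  missing <- setdiff(
    utils::combn(base$nodes, 2, paste, collapse = "|"),
    paste(base$edges$from, base$edges$to, sep = "|")
  )
  pick <- strsplit(missing[1], "|", fixed = TRUE)[[1]]
  grown <- ppi_network(rbind(as.data.frame(base$edges),
                             data.frame(from = pick[1], to = pick[2])),
                       nodes = base$nodes, disease_id = "grown")
  deg1 <- node_degree(grown)
  joined <- dplyr::left_join(deg0, deg1, by = "node")
  expect_true(all(joined$degree.y >= joined$degree.x))
})
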