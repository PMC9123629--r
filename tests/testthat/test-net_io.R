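test_that("edge list reading deduplicates, drops self-loops, tolerates scores", {
  f <- withr::local_tempfile(lines = c("A\tB", "B\tA", "A\tA", "B\tC"))
  expect_warning(net <- read_edge_list(f, "demo"), "self-loop")
  expect_setequal(net$nodes, c("A", "B", "C"))
  expect_identical(net$edges, tibble::tibble(from = c("A", "B"), to = c("B", "C")))

  f2 <- withr::local_tempfile(lines = c("A\tB\t0.91", "# a comment", "B\tC\t0.10"))
  net2 <- read_edge_list(f2, "demo")
  expect_identical(net2$edges$from, c("A", "B"))
  expect_equal(n_edges(net2), 2L)
})

test_that("degenerate and malformed edge lists are handled", {
  empty <- withr::local_tempfile(lines = character())
  expect_warning(net <- read_edge_list(empty, "demo"), "no edges")
  expect_identical(net$nodes, character(0))
  expect_identical(n_edges(net), 0L)

  bad <- withr::local_tempfile(lines = c("A\tB", "LONELYTOKEN"))
  expect_error(read_edge_list(bad, "demo"), "Line 2",
               class = "hubscreen_parse_error")
  expect_error(read_edge_list(file.path(tempdir(), "nope-missing.tsv")),
               class = "hubscreen_io_error")
})

test_that("STRING dialect: header skipped, symmetric duplicates collapse", {
  f <- withr::local_tempfile(lines = c(
    "node1\tnode2\tcombined_score",
    "TP53\tAKT1\t0.99",
    "AKT1\tTP53\t0.99",
    "TP53\tEGFR\t0.42"
  ))
  net <- read_string_links(f, "eso")
  expect_setequal(net$nodes, c("AKT1", "EGFR", "TP53"))
  expect_equal(n_edges(net), 2L)

  headerless <- withr::local_tempfile(lines = c("A\tB\t0.5", "B\tC\t0.7"))
  expect_message(net2 <- read_string_links(headerless, "x"), "No header")
  expect_equal(n_edges(net2), 2L)
})

test_that("reader output is independent of row order and endpoint order", {
  lines <- c("A\tB", "C\tB", "A\tD")
  f1 <- withr::local_tempfile(lines = lines)
  f2 <- withr::local_tempfile(lines = rev(c("B\tA", "B\tC", "D\tA")))
  n1 <- read_edge_list(f1, "x")
  n2 <- read_edge_list(f2, "x")
  expect_identical(n1$edges, n2$edges)
  expect_identical(n1$nodes, n2$nodes)
})

test_that("write/read round trip preserves node and edge sets exactly", {
  for (seed in c(11L, 12L)) {
    net <- random_network(12, 0.25, seed, isolated = TRUE)
    for (style in c("plain", "string")) {
      f <- withr::local_tempfile()
      write_edge_list(net, f, style = style)
      back <- if (style == "string") read_string_links(f, net$disease_id) else
        read_edge_list(f, net$disease_id)
      expect_identical(back$nodes, net$nodes)
      expect_identical(back$edges, net$edges)
    }
  }
})

test_that("generated STRING-style files round-trip the manifest counts", {
  cfg <- scenario_config(seed = 5L)
  scen <- generate_scenario(cfg)
  dir <- withr::local_tempdir()
  paths <- write_scenario(scen, dir, style = "string")
  for (i in seq_along(paths$network_paths)) {
    net <- read_string_links(paths$network_paths[[i]],
                             names(paths$network_paths)[i])
    expect_equal(n_nodes(net), scen$manifest$networks[[i]]$n_nodes)
    expect_equal(n_edges(net), scen$manifest$networks[[i]]$n_edges)
  }
  acts <- read_action_table(paths$action_path)
  expect_identical(acts, scen$actions)
})

test_that("action tables parse modes and flags strictly", {
  f <- withr::local_tempfile(lines = c(
    "source\ttarget\tmode\tdirected",
    "EGF\tEGFR\tactivation\ttrue",
    "TP53\tMYC\tinhibition\t0",
    "JUN\tFOS\texpression\tyes"
  ))
  acts <- read_action_table(f)
  expect_identical(acts$mode, c("activation", "inhibition", "expression"))
  expect_identical(acts$directed, c(TRUE, FALSE, TRUE))

  bad <- withr::local_tempfile(lines = "X\tY\tbinding\ttrue")
  err <- expect_error(read_action_table(bad),
                      class = "hubscreen_validation_error")
  expect_match(conditionMessage(err), "activation, inhibition, expression")

  loop <- withr::local_tempfile(lines = "X\tX\tactivation\ttrue")
  expect_error(read_action_table(loop), class = "hubscreen_validation_error")

  empty <- withr::local_tempfile(lines = character())
  expect_identical(nrow(read_action_table(empty)), 0L)
})

test_that("node tables are written sorted with 3-decimal display values", {
  recs <- tibble::tibble(
    node = c("AKT1", "BBB", "AAA"),
    degree = c(59L, 12L, 12L),
    betweenness = c(0.0091234, 0.5, 0),
    closeness = c(0.684, 0.25, 0.1),
    stress = c(1300, 4, 0)
  )
  f <- withr::local_tempfile()
  write_node_table(recs, f)
  lines <- readLines(f)
  expect_identical(lines[1], "node,degree,betweenness,closeness,stress")
  expect_identical(lines[2], "AKT1,59,0.009,0.684,1300")
  # equal degrees ordered lexicographically
  expect_identical(substr(lines[3], 1, 3), "AAA")
  expect_identical(substr(lines[4], 1, 3), "BBB")

  single <- write_node_table(recs[1, ], withr::local_tempfile())
  expect_length(readLines(single), 2L)
  expect_error(write_node_table(recs[0, ], f),
               class = "hubscreen_validation_error")
})
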