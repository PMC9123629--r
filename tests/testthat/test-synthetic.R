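test_that("scenario configuration enforces its invariants", {
  expect_error(scenario_config(shared_labels = 120),
               class = "hubscreen_validation_error")
  expect_error(scenario_config(hublike_shared = 50, shared_labels = 42),
               class = "hubscreen_validation_error")
  expect_error(scenario_config(target_edges = 10^6),
               class = "hubscreen_validation_error")
  expect_error(
    scenario_config(action_isolation_plan = list(expression = "NOT_A_LABEL")),
    class = "hubscreen_validation_error"
  )
  cfg <- scenario_config()
  expect_identical(cfg$target_edges, c(1484L, 2164L, 2012L))
  expect_length(cfg$shared, 42L)
  expect_length(cfg$hublike, 36L)
  expect_length(cfg$superhubs, 3L)
})

test_that("generation is deterministic and seed-sensitive", {
  cfg <- scenario_config(seed = 4L)
  n1 <- generate_network(cfg, 1L)
  n2 <- generate_network(cfg, 1L)
  expect_identical(n1, n2)

  other_seed <- generate_network(scenario_config(seed = 5L), 1L)
  expect_false(identical(n1$edges, other_seed$edges))
  expect_identical(n1$nodes, other_seed$nodes) # planted labels fixed

  other_index <- generate_network(cfg, 2L)
  expect_false(identical(n1$edges, other_index$edges))
})

test_that("edge counts hit the target exactly and tails are heavy", {
  for (seed in 1:5) {
    cfg <- scenario_config(seed = seed, target_edges = 1500L)
    net <- generate_network(cfg, 1L)
    expect_identical(n_edges(net), 1500L)
    deg <- node_degree(net)$degree
    expect_gte(max(deg), 3 * stats::median(deg))
  }
})

test_that("planted super-hubs rank in the top 10% of their own network", {
  hits <- 0L
  for (seed in 1:10) {
    cfg <- scenario_config(seed = seed)
    for (i in 1:3) {
      tbl <- centrality_table(generate_network(cfg, i))
      top10 <- top_percent(tbl, 10)$node
      hits <- hits + as.integer(all(cfg$superhubs %in% top10))
    }
  }
  expect_gte(hits, 29L) # >= 95% of the 30 generated networks
})

test_that("trio manifests describe the generated networks", {
  cfg <- scenario_config(seed = 8L)
  trio <- generate_trio(cfg)
  expect_length(trio$networks, 3L)
  for (i in 1:3) {
    expect_identical(n_nodes(trio$networks[[i]]),
                     trio$manifest$networks[[i]]$n_nodes)
    expect_identical(n_edges(trio$networks[[i]]),
                     trio$manifest$networks[[i]]$n_edges)
    expect_true(all(trio$manifest$shared %in% trio$networks[[i]]$nodes))
  }
  # non-shared labels are disease-unique
  uniq <- lapply(trio$networks, function(nw) {
    setdiff(nw$nodes, trio$manifest$shared)
  })
  expect_length(Reduce(intersect, uniq), 0L)
  expect_identical(trio$manifest$expected$core, 18L)
  expect_identical(trio$manifest$expected$critical, 1L)
})

test_that("a shared-free scenario empties the funnel at stage one", {
  cfg <- scenario_config(n_per_network = 30, target_edges = 100L,
                         shared_labels = 0, hublike_shared = 0,
                         superhub_shared = 0, seed = 2L)
  trio <- generate_trio(cfg)
  expect_length(common_proteins(trio$networks), 0L)
})

test_that("action fixtures isolate exactly the planned labels", {
  cand <- sprintf("X%02d", 1:10)
  plan <- list(expression = cand[1:3], inhibition = cand[4])
  acts <- generate_action_fixture(cand, plan, seed = 6L)
  map <- build_action_map(cand, acts)
  expect_setequal(isolated_in_layer(map, "expression"), cand[1:3])
  expect_identical(isolated_in_layer(map, "inhibition"), cand[4])
  expect_length(isolated_in_layer(map, "activation"), 0L)
  expect_true(all(c(acts$source, acts$target) %in% cand))

  expect_error(generate_action_fixture(cand, list(expression = "ZZ")),
               class = "hubscreen_validation_error")
  none <- generate_action_fixture(cand, list(), seed = 1L)
  expect_identical(screen_by_isolation(build_action_map(cand, none))$core, cand)
  all_iso <- generate_action_fixture(cand, list(
    activation = cand, inhibition = cand, expression = cand
  ), seed = 1L)
  expect_identical(nrow(all_iso), 0L)
  expect_length(screen_by_isolation(build_action_map(cand, all_iso))$core, 0L)
})

test_that("written scenarios are byte-identical across runs", {
  cfg <- scenario_config(seed = 13L)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_scenario(generate_scenario(cfg), d1)
  write_scenario(generate_scenario(cfg), d2)
  f1 <- list.files(d1, full.names = TRUE)
  f2 <- list.files(d2, full.names = TRUE)
  expect_identical(basename(f1), basename(f2))
  for (i in seq_along(f1)) {
    expect_identical(readLines(f1[i]), readLines(f2[i]))
  }
})
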