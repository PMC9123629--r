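#' Configure a synthetic cross-disease screening scenario
#'
#' Describes a trio (by default) of disease interactomes with planted ground
#' truth, emulating STRING-derived disease networks: each network has
#' `n_per_network` proteins and an exact target edge count, a shared label
#' subset appears in every network, and designated shared labels are planted
#' to rank as hubs. Defaults reproduce the study conditions of a
#' three-cancer screen: 100 proteins per disease connected by 1484, 2164 and
#' 2012 undirected edges, 42 shared proteins of which 36 are hub-like (top
#' 50% by degree) in every network, 3 shared super-hubs (top 10% everywhere),
#' and an action-map isolation plan under which 18 of the 36 hub-like
#' candidates survive and exactly one super-hub remains critical.
#'
#' Networks grow by preferential attachment (each new node attaches to `m`
#' existing nodes with probability proportional to current degree), which
#' yields the heavy-tailed, scale-free degree structure of disease
#' interactomes. Planting uses tiered attachment weights: shared super-hubs
#' and per-disease local hubs multiply their degree by `superhub_boost` when
#' attracting attachments, hub-like shared labels by `hublike_boost`, and the
#' remaining shared labels are added last with only `low_attach` attachments
#' so they stay below the hub-like cut. Local hubs (disease-unique boosted
#' labels filling the non-shared top-10% slots) make the cross-disease hub
#' intersection recover exactly the planted super-hubs.
#'
#' @param n_per_network Number of proteins in each disease network.
#' @param n_networks Number of disease networks (the screen needs >= 2).
#' @param target_edges Integer vector (length 1 or `n_networks`) of exact
#'   undirected edge counts per network.
#' @param shared_labels Number of proteins present in every network.
#' @param hublike_shared Number of shared proteins planted into the top 50%
#'   by degree of every network (includes the super-hubs).
#' @param superhub_shared Number of shared proteins planted into the top 10%
#'   by degree of every network.
#' @param disease_ids Optional character vector of disease labels.
#' @param action_isolation_plan Named list (`activation`, `inhibition`,
#'   `expression`) of planted hub-like labels to isolate per layer; `NULL`
#'   selects the default plan (the study-shaped plan when `hublike_shared ==
#'   36` and `superhub_shared == 3`, otherwise no isolation).
#' @param seed Master seed; all generation is deterministic given the
#'   configuration and seed.
#' @param superhub_boost,hublike_boost,low_attach Planting parameters (see
#'   Details); the defaults are part of the scenario definition.
#' @return An object of class `scenario_config` (a validated list, including
#'   the planted label vectors).
#' @export
scenario_config <- function(n_per_network = 100L,
                            n_networks = 3L,
                            target_edges = c(1484L, 2164L, 2012L),
                            shared_labels = 42L,
                            hublike_shared = 36L,
                            superhub_shared = 3L,
                            disease_ids = NULL,
                            action_isolation_plan = NULL,
                            seed = 1L,
                            superhub_boost = 10,
                            hublike_boost = 2,
                            low_attach = 3L) {
  n <- as.integer(n_per_network)
  k_net <- as.integer(n_networks)
  s <- as.integer(shared_labels)
  h <- as.integer(hublike_shared)
  k <- as.integer(superhub_shared)
  if (k_net < 1L || n < 2L) {
    abort_validation("Need `n_networks` >= 1 and `n_per_network` >= 2.")
  }
  if (!(k >= 0L && k <= h && h <= s && s <= n)) {
    abort_validation(
      "Need 0 <= superhub_shared <= hublike_shared <= shared_labels <= n_per_network."
    )
  }
  target_edges <- as.integer(target_edges)
  if (length(target_edges) == 1L) target_edges <- rep(target_edges, k_net)
  if (length(target_edges) != k_net) {
    abort_validation("`target_edges` must have length 1 or `n_networks`.")
  }
  max_edges <- n * (n - 1) / 2
  if (any(target_edges < n - 1L) || any(target_edges > max_edges)) {
    abort_validation(sprintf(
      "Each target edge count must lie in [n - 1, n(n-1)/2] = [%d, %d].",
      n - 1L, max_edges
    ))
  }
  disease_ids <- disease_ids %||% sprintf("disease%02d", seq_len(k_net))
  if (length(disease_ids) != k_net || anyDuplicated(disease_ids) > 0L) {
    abort_validation("`disease_ids` must be `n_networks` distinct labels.")
  }

  superhubs <- if (k > 0L) sprintf("SHB%02d", seq_len(k)) else character()
  hublike_rest <- if (h > k) sprintf("HLK%02d", seq.int(k + 1L, h)) else character()
  low_shared <- if (s > h) sprintf("CMN%02d", seq.int(h + 1L, s)) else character()
  hublike <- c(superhubs, hublike_rest)
  shared <- c(hublike, low_shared)

  n_unique <- n - s
  local_hubs_n <- min(max(0L, as.integer(ceiling(0.10 * n)) - k), n_unique)
  if (is.null(action_isolation_plan)) {
    action_isolation_plan <- default_isolation_plan(superhubs, hublike_rest)
  }
  plan <- validate_isolation_plan(action_isolation_plan, hublike)

  structure(
    list(
      n_per_network = n, n_networks = k_net, target_edges = target_edges,
      shared_labels = s, hublike_shared = h, superhub_shared = k,
      disease_ids = disease_ids, seed = as.integer(seed),
      superhub_boost = superhub_boost, hublike_boost = hublike_boost,
      low_attach = as.integer(low_attach),
      superhubs = superhubs, hublike = hublike, low_shared = low_shared,
      shared = shared, n_unique = n_unique, local_hubs_n = local_hubs_n,
      action_isolation_plan = plan
    ),
    class = "scenario_config"
  )
}

# Study-shaped default: expression isolates 6 hub-like labels, activation 2
# of those 6, inhibition the first 5 of the 6 plus 12 others (among them the
# two non-surviving super-hubs), so 18 of 36 candidates survive and exactly
# one super-hub stays critical.
default_isolation_plan <- function(superhubs, hublike_rest) {
  if (length(superhubs) != 3L || length(hublike_rest) != 33L) {
    return(list(activation = character(), inhibition = character(),
                expression = character()))
  }
  expr6 <- hublike_rest[1:6]
  list(
    activation = expr6[1:2],
    inhibition = c(expr6[1:5], superhubs[2:3], hublike_rest[7:16]),
    expression = expr6
  )
}

validate_isolation_plan <- function(plan, hublike) {
  if (!is.list(plan)) {
    abort_validation("`action_isolation_plan` must be a named list of label vectors.")
  }
  unknown <- setdiff(names(plan), action_modes())
  if (length(unknown) > 0L) {
    abort_validation(sprintf(
      "Isolation plan layer(s) %s are not action modes.",
      paste0("'", unknown, "'", collapse = ", ")
    ))
  }
  full <- map(rlang::set_names(action_modes()), function(m) {
    as.character(plan[[m]] %||% character())
  })
  stray <- setdiff(unlist(full, use.names = FALSE), hublike)
  if (length(stray) > 0L) {
    abort_validation(sprintf(
      "Isolation plan references non-candidate label(s): %s.",
      paste(stray, collapse = ", ")
    ))
  }
  full
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %d networks x %d nodes; edges %s; shared %d (hub-like %d, super-hubs %d); seed %d\n",
    x$n_networks, x$n_per_network, paste(x$target_edges, collapse = "/"),
    x$shared_labels, x$hublike_shared, x$superhub_shared, x$seed
  ))
  invisible(x)
}

# Disease-unique label vectors; boosted local hubs first.
unique_labels <- function(config, index) {
  id <- toupper(gsub("[^A-Za-z0-9]", "", config$disease_ids[index]))
  nh <- config$local_hubs_n
  nu <- config$n_unique - nh
  list(
    local_hubs = if (nh > 0L) sprintf("%s_H%02d", id, seq_len(nh)) else character(),
    regular = if (nu > 0L) sprintf("%s_U%02d", id, seq_len(nu)) else character()
  )
}

#' Generate one synthetic disease network
#'
#' Grows a scale-free network for disease `index` of a scenario by
#' preferential attachment with tiered attachment weights (see
#' [scenario_config()]). The edge count equals the configured target
#' exactly; generation is deterministic for a given `(seed, index)`.
#'
#' @param config A [scenario_config()].
#' @param index Which network to generate (1-based).
#' @return A [ppi_network()].
#' @export
generate_network <- function(config, index = 1L) {
  stopifnot(inherits(config, "scenario_config"))
  index <- as.integer(index)
  if (index < 1L || index > config$n_networks) {
    abort_validation("`index` must address one of the configured networks.")
  }
  n <- config$n_per_network
  target <- config$target_edges[index]
  uniq <- unique_labels(config, index)

  withr::with_seed(derive_seed(config$seed, index), {
    regular <- sample(uniq$regular)
    # Node insertion order: boosted labels first, planted hub-like next,
    # regular disease-unique nodes, low-degree shared labels last.
    order_labels <- c(config$superhubs, uniq$local_hubs,
                      setdiff(config$hublike, config$superhubs),
                      regular, config$low_shared)
    stopifnot(length(order_labels) == n)
    n_low <- length(config$low_shared)
    weight_tbl <- c(
      rep(config$superhub_boost,
          length(config$superhubs) + length(uniq$local_hubs)),
      rep(config$hublike_boost, config$hublike_shared - config$superhub_shared),
      rep(1, length(regular)),
      rep(1, n_low)
    )

    n_planted <- length(config$superhubs) + length(uniq$local_hubs) +
      (config$hublike_shared - config$superhub_shared)
    plan <- attachment_plan(n, target, n_planted, n_low, config$low_attach)
    m0 <- plan$m0
    m_vec <- plan$m_vec

    deg <- integer(n)
    deg[seq_len(m0)] <- m0 - 1L
    e_from <- integer(target)
    e_to <- integer(target)
    ne <- 0L
    if (m0 >= 2L) {
      clique <- utils::combn(m0, 2L)
      ne <- ncol(clique)
      e_from[seq_len(ne)] <- clique[1L, ]
      e_to[seq_len(ne)] <- clique[2L, ]
    }
    if (m0 < n) {
      for (t in seq.int(m0 + 1L, n)) {
        mi <- m_vec[t]
        existing <- seq_len(t - 1L)
        w <- (deg[existing] + 1e-9) * weight_tbl[existing]
        targets <- if (mi >= t - 1L) existing else
          sample(existing, mi, prob = w)
        deg[targets] <- deg[targets] + 1L
        deg[t] <- length(targets)
        idx <- ne + seq_along(targets)
        e_from[idx] <- targets
        e_to[idx] <- t
        ne <- ne + length(targets)
      }
    }
    stopifnot(ne == target)
    ppi_network(
      tibble(from = order_labels[e_from], to = order_labels[e_to]),
      nodes = order_labels,
      disease_id = config$disease_ids[index]
    )
  })
}

# Decide the clique size m0 = m + 1 and per-position attachment counts so the
# final edge count hits `target` exactly. Node positions fall in three
# classes: the first `n_planted` positions (planted hub-like and boosted
# labels) attach with m plus a premium (so late planted nodes are born with a
# degree head start over disease-unique nodes), the last `n_low` positions
# attach with `low_attach`, and the rest with m. A remainder of +/-1
# adjustments is spread deterministically to land on the target exactly.
attachment_plan <- function(n, target, n_planted, n_low, low_attach) {
  premium <- function(m) max(2L, as.integer(round(0.4 * m)))
  counts <- function(m) {
    m0 <- m + 1L
    n_low_eff <- min(n_low, n - m0)
    n_pl <- min(max(0L, n_planted - m0), n - m0 - n_low_eff)
    n_reg <- n - m0 - n_low_eff - n_pl
    list(m0 = m0, n_pl = n_pl, n_reg = n_reg, n_low = n_low_eff)
  }
  expected <- function(m) {
    if (m + 1L > n) return(Inf)
    cc <- counts(m)
    choose(cc$m0, 2L) + cc$n_pl * min(m + premium(m), n - 1L) +
      cc$n_reg * m + cc$n_low * min(low_attach, m)
  }
  m <- 1L
  while (m + 1L < n && expected(m + 1L) <= target) m <- m + 1L
  cc <- counts(m)
  m0 <- cc$m0
  m_vec <- integer(n)
  later <- if (m0 < n) seq.int(m0 + 1L, n) else integer()
  pl_pos <- if (cc$n_pl > 0L) seq.int(m0 + 1L, m0 + cc$n_pl) else integer()
  reg_pos <- if (cc$n_reg > 0L) {
    seq.int(m0 + cc$n_pl + 1L, m0 + cc$n_pl + cc$n_reg)
  } else integer()
  low_pos <- if (cc$n_low > 0L) seq.int(n - cc$n_low + 1L, n) else integer()
  m_vec[pl_pos] <- pmin(m + premium(m), pl_pos - 1L)
  m_vec[reg_pos] <- pmin(m, reg_pos - 1L)
  m_vec[low_pos] <- pmin(min(low_attach, m), low_pos - 1L)
  deficit <- target - (choose(m0, 2L) + sum(m_vec[later]))
  # Capacity: node t can attach to at most t - 1 predecessors. Surplus goes
  # first to planted then regular positions; shortfall comes off regular
  # positions first, low-attachment positions last.
  bump_order <- c(pl_pos, reg_pos, low_pos)
  trim_order <- c(rev(reg_pos), rev(pl_pos), rev(low_pos))
  while (deficit > 0L) {
    progressed <- FALSE
    for (t in bump_order) {
      if (deficit == 0L) break
      if (m_vec[t] < t - 1L) {
        m_vec[t] <- m_vec[t] + 1L
        deficit <- deficit - 1L
        progressed <- TRUE
      }
    }
    if (deficit > 0L && !progressed) {
      abort_validation("Edge target is infeasible for this configuration.")
    }
  }
  while (deficit < 0L) {
    progressed <- FALSE
    for (t in trim_order) {
      if (deficit == 0L) break
      if (m_vec[t] > 1L) {
        m_vec[t] <- m_vec[t] - 1L
        deficit <- deficit + 1L
        progressed <- TRUE
      }
    }
    if (deficit < 0L && !progressed) {
      abort_validation("Edge target is infeasible for this configuration.")
    }
  }
  list(m0 = m0, m_vec = m_vec)
}

#' Generate the disease-network trio and its ground-truth manifest
#'
#' Generates every network of the scenario plus a manifest recording the
#' planted truth: per-network node and edge counts, the shared, hub-like and
#' super-hub label lists, the per-layer isolation plan, and the expected
#' funnel counts. The manifest fully determines the expected output of
#' [run_screen()] on the generated data.
#'
#' @param config A [scenario_config()].
#' @return A list with elements `networks` (list of [ppi_network()]) and
#'   `manifest` (see Details).
#' @export
generate_trio <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  networks <- map(seq_len(config$n_networks), function(i) {
    generate_network(config, i)
  })
  plan <- config$action_isolation_plan
  removed <- sort(unique(unlist(plan, use.names = FALSE)))
  core_labels <- setdiff(config$hublike, removed)
  critical_labels <- intersect(config$superhubs, core_labels)
  manifest <- list(
    seed = config$seed,
    networks = map(networks, function(nw) {
      list(disease_id = nw$disease_id, n_nodes = n_nodes(nw),
           n_edges = n_edges(nw))
    }),
    shared = config$shared,
    hublike = config$hublike,
    superhubs = config$superhubs,
    low_shared = config$low_shared,
    isolation_plan = plan,
    expected = list(
      common = length(config$shared),
      hublike = length(config$hublike),
      core = length(core_labels),
      critical = length(critical_labels),
      core_labels = core_labels,
      critical_labels = critical_labels
    )
  )
  list(networks = networks, manifest = manifest)
}

#' Generate a regulatory action fixture with planned isolation
#'
#' Builds an action-edge table over a candidate set such that, in each
#' layer, exactly the planned labels are isolated: every other candidate
#' receives at least one incident edge of that mode (a randomly ordered path
#' through the non-isolated candidates), and edges never touch a planned
#' isolate. All edges are within the candidate set and directed.
#'
#' @param candidates Character vector of candidate proteins.
#' @param isolation_plan Named list (`activation`, `inhibition`,
#'   `expression`) of candidate labels to isolate per layer; missing layers
#'   isolate nobody.
#' @param seed Integer seed for the random path orders.
#' @return A tibble of action edges (`source`, `target`, `mode`,
#'   `directed`).
#' @export
generate_action_fixture <- function(candidates, isolation_plan = list(),
                                    seed = 1L) {
  candidates <- sort(unique(as.character(candidates)))
  plan <- validate_isolation_plan(isolation_plan, candidates)
  withr::with_seed(as.integer(seed), {
    layers <- map(rlang::set_names(action_modes()), function(m) {
      connected <- setdiff(candidates, plan[[m]])
      if (length(connected) < 2L) {
        if (length(connected) == 1L) {
          warn(sprintf(
            "Layer '%s' has a single non-isolated candidate; it cannot receive an edge and will screen as isolated.",
            m
          ), class = "hubscreen_warning")
        }
        return(tibble(source = character(), target = character(),
                      mode = character(), directed = logical()))
      }
      ord <- sample(connected)
      tibble(
        source = ord[-length(ord)],
        target = ord[-1L],
        mode = m,
        directed = TRUE
      )
    })
    bind_rows(layers)
  })
}

#' Generate a complete screening scenario (networks, actions, manifest)
#'
#' Convenience wrapper: [generate_trio()] plus a
#' [generate_action_fixture()] over the planted hub-like labels using the
#' configured isolation plan.
#'
#' @param config A [scenario_config()].
#' @return An object of class `screen_scenario`: list with `networks`,
#'   `actions`, `manifest` and `config`.
#' @export
generate_scenario <- function(config = scenario_config()) {
  trio <- generate_trio(config)
  actions <- generate_action_fixture(
    config$hublike, config$action_isolation_plan,
    seed = derive_seed(config$seed, config$n_networks + 1L)
  )
  structure(
    list(networks = trio$networks, actions = actions,
         manifest = trio$manifest, config = config),
    class = "screen_scenario"
  )
}

#' Write a generated scenario to disk
#'
#' Writes one edge-list file per network, the action table, and the
#' ground-truth manifest as YAML. Output is byte-identical across runs for
#' the same configuration and seed.
#'
#' @param scenario A [generate_scenario()] result.
#' @param dir Output directory (created if needed).
#' @param style Edge-list dialect, `"plain"` or `"string"` (see
#'   [write_edge_list()]).
#' @return Invisibly, a list with `network_paths` (named by disease),
#'   `action_path` and `manifest_path`.
#' @export
write_scenario <- function(scenario, dir, style = c("plain", "string")) {
  stopifnot(inherits(scenario, "screen_scenario"))
  style <- match.arg(style)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    abort_io(sprintf("Cannot create directory '%s'.", dir))
  }
  network_paths <- map_chr(scenario$networks, function(nw) {
    p <- file.path(dir, paste0(nw$disease_id, "_links.tsv"))
    write_edge_list(nw, p, style = style)
    p
  })
  names(network_paths) <- map_chr(scenario$networks, "disease_id")
  action_path <- file.path(dir, "actions.tsv")
  write_action_table(scenario$actions, action_path)
  manifest_path <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(scenario$manifest, manifest_path)
  invisible(list(network_paths = network_paths, action_path = action_path,
                 manifest_path = manifest_path))
}
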