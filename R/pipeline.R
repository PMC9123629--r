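#' Run the full cross-disease screening funnel
#'
#' Executes the staged screen: load the disease networks, compute per-node
#' centralities, intersect node sets across diseases (common proteins), keep
#' the common proteins that are hub-like (top `hublike_pct`% by degree) in
#' every network, remove hub-like candidates isolated in any selected
#' action layer (action core), select the common hubs (top `hub_pct`%
#' everywhere), and intersect core with hubs to obtain the critical
#' proteins.
#'
#' @param networks Either a named character vector of edge-list file paths
#'   (names are disease ids; STRING-style headers are auto-detected) or a
#'   list of [ppi_network()] objects. At least two networks are required.
#' @param actions Optional: path to an action table, or a tibble of action
#'   edges. When absent the action screen is skipped and the core equals the
#'   hub-like common set (flagged in the result).
#' @param hub_pct Degree percentile defining hubs (default 10).
#' @param hublike_pct Degree percentile defining hub-like nodes (default
#'   50).
#' @param layers Action layers used by the isolation screen (default all
#'   three).
#' @param tie_policy Percentile tie policy, see [top_percent()].
#' @param hub_scope `"all"` (default) requires hub rank in every network;
#'   `"any"` in at least one.
#' @return An object of class `screen_result` with elements `centrality`
#'   (named list of per-disease tibbles), `common_set`, `hublike_common`,
#'   `action_core`, `common_hubs`, `critical_set`, `outcome` (the
#'   [screen_by_isolation()] result, or `NULL`), `action_screened` flag,
#'   `funnel` (tibble of stage counts) and `params`. Funnel counts are
#'   non-increasing across common -> hublike -> core, and the critical set is
#'   contained in both the core and the hub set.
#' @examples
#' scen <- generate_scenario(scenario_config(seed = 42))
#' res <- run_screen(scen$networks, scen$actions)
#' res
#' @export
run_screen <- function(networks, actions = NULL, hub_pct = 10,
                       hublike_pct = 50, layers = action_modes(),
                       tie_policy = "strict", hub_scope = c("all", "any")) {
  hub_scope <- match.arg(hub_scope)

  nets <- with_stage("load networks", load_networks(networks))
  if (length(nets) < 2L) {
    abort_validation("The screen needs at least two disease networks.")
  }
  disease_ids <- map_chr(nets, "disease_id")
  if (anyDuplicated(disease_ids) > 0L) {
    abort_validation("Disease ids must be distinct across networks.")
  }

  tables <- with_stage("centrality", {
    rlang::set_names(map(nets, centrality_table), disease_ids)
  })
  common <- with_stage("common proteins", common_proteins(nets))
  if (length(common) == 0L) {
    warn("No proteins are shared by all networks; downstream sets are empty.",
         class = "hubscreen_warning")
  }
  hublike <- with_stage("hub-like screen", {
    common_hublike(tables, common, percentile = hublike_pct,
                   tie_policy = tie_policy)
  })

  action_tbl <- with_stage("action map", load_actions(actions))
  if (is.null(action_tbl)) {
    outcome <- NULL
    core <- hublike
  } else {
    outcome <- with_stage("action map", {
      screen_by_isolation(build_action_map(hublike, action_tbl), modes = layers)
    })
    core <- outcome$core
  }

  hubs <- with_stage("hub screen", {
    common_hubs(tables, common, percentile = hub_pct,
                tie_policy = tie_policy, scope = hub_scope)
  })
  critical <- critical_proteins(core, hubs)

  funnel <- tibble(
    stage = c("common", "hublike", "core", "critical"),
    count = c(length(common), length(hublike), length(core), length(critical))
  )
  stopifnot(all(diff(funnel$count[1:3]) <= 0),
            all(critical %in% core),
            all(critical %in% hubs))

  structure(
    list(
      centrality = tables,
      common_set = as.character(common),
      hublike_common = hublike,
      action_core = core,
      common_hubs = hubs,
      critical_set = critical,
      outcome = outcome,
      action_screened = !is.null(outcome),
      funnel = funnel,
      params = list(hub_pct = hub_pct, hublike_pct = hublike_pct,
                    layers = as.character(layers), tie_policy = tie_policy,
                    hub_scope = hub_scope, diseases = disease_ids)
    ),
    class = "screen_result"
  )
}

load_networks <- function(networks) {
  if (is.character(networks)) {
    if (is.null(names(networks)) || any(!nzchar(names(networks)))) {
      abort_validation("Network file paths must be named by disease id.")
    }
    Map(function(path, id) read_string_links(path, disease_id = id),
        networks, names(networks), USE.NAMES = FALSE)
  } else if (is.list(networks)) {
    networks
  } else {
    abort_validation(
      "`networks` must be named file paths or a list of `ppi_network`s."
    )
  }
}

load_actions <- function(actions) {
  if (is.null(actions)) return(NULL)
  if (is.character(actions)) return(read_action_table(actions))
  if (is.data.frame(actions)) return(actions)
  abort_validation("`actions` must be a file path, a data frame, or NULL.")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("<screen_result> %d networks (%s)\n",
              length(x$centrality), paste(x$params$diseases, collapse = ", ")))
  with(x$funnel, cat(sprintf("  %-8s %4d\n", stage, count), sep = ""))
  if (!x$action_screened) cat("  (action screen skipped: no action table)\n")
  if (length(x$critical_set) > 0L) {
    cat("  critical:", paste(x$critical_set, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write a screening report directory
#'
#' Writes, into `out_dir`: one node centrality table per disease
#' (`nodes_<disease>.csv`, display precision per [write_node_table()]), the
#' funnel summary (`funnel.csv`), the action screen status table
#' (`action_screen.csv`, when the action screen ran), and for each critical
#' protein a cross-disease table `critical_<protein>.csv` with columns
#' `disease`, `degree`, `degree_max` (the network's maximum degree),
#' `betweenness`, `closeness` (3 decimal places), `stress`, plus
#' full-precision columns `betweenness_full` and `closeness_full`. Rerunning
#' on the same result produces byte-identical files.
#'
#' @param result A [run_screen()] result.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the character vector of files written.
#' @export
make_report <- function(result, out_dir) {
  stopifnot(inherits(result, "screen_result"))
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE)) {
    abort_io(sprintf("Cannot create directory '%s'.", out_dir))
  }
  written <- character()
  for (id in names(result$centrality)) {
    p <- file.path(out_dir, sprintf("nodes_%s.csv", id))
    write_node_table(result$centrality[[id]], p)
    written <- c(written, p)
  }
  p <- file.path(out_dir, "funnel.csv")
  write_csv_safe(result$funnel, p)
  written <- c(written, p)
  if (result$action_screened) {
    p <- file.path(out_dir, "action_screen.csv")
    write_screen_outcome(result$outcome, p)
    written <- c(written, p)
  }
  if (length(result$critical_set) == 0L) {
    inform("No critical proteins; no per-protein tables written.")
  }
  for (protein in result$critical_set) {
    tab <- critical_protein_table(result, protein)
    p <- file.path(out_dir, sprintf("critical_%s.csv", protein))
    write_csv_safe(tab, p)
    written <- c(written, p)
  }
  invisible(written)
}

#' Cross-disease centrality table for one protein
#'
#' One row per disease: the protein's degree alongside the network's maximum
#' degree, betweenness and closeness at 3-decimal display precision with
#' full-precision companions, and stress.
#'
#' @param result A [run_screen()] result.
#' @param protein A protein symbol present in the analysed networks.
#' @return A tibble with one row per disease.
#' @export
critical_protein_table <- function(result, protein) {
  stopifnot(inherits(result, "screen_result"))
  check_string(protein, "protein")
  rows <- imap(result$centrality, function(tbl, id) {
    hit <- tbl[tbl$node == protein, ]
    if (nrow(hit) == 0L) return(NULL)
    tibble(
      disease = id,
      degree = hit$degree,
      degree_max = max(tbl$degree),
      betweenness = sprintf("%.3f", hit$betweenness),
      closeness = sprintf("%.3f", hit$closeness),
      stress = round(hit$stress),
      betweenness_full = hit$betweenness,
      closeness_full = hit$closeness
    )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0L) {
    abort_validation(sprintf("Protein '%s' is absent from every network.",
                             protein))
  }
  out
}
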