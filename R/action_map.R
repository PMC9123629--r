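#' Build a layered regulatory action map over a candidate set
#'
#' Restricts a table of typed directed action edges (activation, inhibition,
#' expression) to a candidate protein set and splits it into per-mode layers.
#' Edges with either endpoint outside the candidate set are discarded (a
#' count is logged): the action screen only asks how the candidates regulate
#' each other.
#'
#' @param candidates Character vector of candidate protein symbols.
#' @param actions A tibble of action edges with columns `source`, `target`,
#'   `mode`, `directed` (see [read_action_table()]).
#' @return An object of class `action_map`: a list with `candidates` (sorted)
#'   and `layers`, a named list of per-mode edge tibbles (one entry per mode
#'   in [action_modes()], possibly empty).
#' @export
build_action_map <- function(candidates, actions = NULL) {
  candidates <- sort(unique(as.character(candidates)))
  if (is.null(actions)) {
    actions <- tibble(source = character(), target = character(),
                      mode = character(), directed = logical())
  }
  if (!is.data.frame(actions) ||
      !all(c("source", "target", "mode") %in% names(actions))) {
    abort_validation(
      "`actions` must have columns source, target, mode (and optionally directed)."
    )
  }
  unknown <- setdiff(unique(actions$mode), action_modes())
  if (length(unknown) > 0L) {
    abort_validation(sprintf(
      "Unknown action mode(s) %s; allowed modes are {%s}.",
      paste0("'", unknown, "'", collapse = ", "),
      paste(action_modes(), collapse = ", ")
    ))
  }
  if (!"directed" %in% names(actions)) {
    actions$directed <- TRUE
  }
  inside <- actions$source %in% candidates & actions$target %in% candidates
  if (any(!inside)) {
    inform(sprintf(
      "Discarded %d action edge(s) with endpoints outside the candidate set.",
      sum(!inside)
    ))
  }
  kept <- actions[inside, c("source", "target", "mode", "directed")]
  layers <- map(rlang::set_names(action_modes()), function(m) {
    as_tibble(kept[kept$mode == m, , drop = FALSE])
  })
  structure(list(candidates = candidates, layers = layers),
            class = "action_map")
}

#' @export
print.action_map <- function(x, ...) {
  cat(sprintf("<action_map> %d candidates\n", length(x$candidates)))
  for (m in names(x$layers)) {
    cat(sprintf("  %-10s %3d edges, %3d isolated\n", m, nrow(x$layers[[m]]),
                length(isolated_in_layer(x, m))))
  }
  invisible(x)
}

#' Candidates isolated in one action layer
#'
#' A candidate is isolated in a layer when it has no incident edge of that
#' mode in either direction — edge direction never affects isolation.
#'
#' @param map An [build_action_map()] result.
#' @param mode One of [action_modes()].
#' @return Sorted character vector of isolated candidates (all candidates
#'   when the layer is empty).
#' @export
isolated_in_layer <- function(map, mode) {
  stopifnot(inherits(map, "action_map"))
  if (!is_string(mode) || !(mode %in% action_modes())) {
    abort_validation(sprintf(
      "`mode` must be one of {%s}.", paste(action_modes(), collapse = ", ")
    ))
  }
  layer <- map$layers[[mode]]
  touched <- unique(c(layer$source, layer$target))
  sort(setdiff(map$candidates, touched))
}

#' Screen candidates by action-layer isolation
#'
#' Applies the isolation-removal rule: a candidate isolated in any of the
#' selected layers is removed; the survivors form the core protein set.
#' With all three layers selected this reproduces the screen in which
#' proteins unconnected in the expression, activation or inhibition map are
#' not considered further.
#'
#' @param map An [build_action_map()] result.
#' @param modes Non-empty subset of [action_modes()]; defaults to all three.
#' @return An object of class `screen_outcome`: list with `removed` (named
#'   list, per selected mode, of isolated candidates) and `core` (sorted
#'   character vector of survivors). `core` plus the union of `removed` is
#'   exactly the candidate set.
#' @export
screen_by_isolation <- function(map, modes = action_modes()) {
  stopifnot(inherits(map, "action_map"))
  modes <- as.character(modes)
  if (length(modes) == 0L || !all(modes %in% action_modes())) {
    abort_validation(sprintf(
      "`modes` must be a non-empty subset of {%s}.",
      paste(action_modes(), collapse = ", ")
    ))
  }
  removed <- map(rlang::set_names(modes), function(m) isolated_in_layer(map, m))
  core <- sort(setdiff(map$candidates, unlist(removed, use.names = FALSE)))
  structure(list(removed = removed, core = core,
                 candidates = map$candidates),
            class = "screen_outcome")
}

#' @export
print.screen_outcome <- function(x, ...) {
  cat(sprintf("<screen_outcome> %d candidates -> %d core\n",
              length(x$candidates), length(x$core)))
  for (m in names(x$removed)) {
    cat(sprintf("  isolated in %-10s: %d\n", m, length(x$removed[[m]])))
  }
  invisible(x)
}

#' Critical proteins: action-core members that are cross-disease hubs
#'
#' The final funnel stage — the intersection of the action-screen core with
#' the common hub (central node) set.
#'
#' @param core Character vector of core proteins (see
#'   [screen_by_isolation()]).
#' @param hubs Character vector of common hub proteins (see
#'   [common_hubs()]).
#' @return Sorted character vector of critical proteins.
#' @export
critical_proteins <- function(core, hubs) {
  sort(intersect(as.character(core), as.character(hubs)))
}

#' Write a screen outcome as a two-column CSV
#'
#' Writes one row per candidate with its status: `core`, or
#' `removed:<mode>` for the first selected layer (in the order the screen was
#' run) in which the candidate was isolated.
#'
#' @param outcome A [screen_by_isolation()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_screen_outcome <- function(outcome, path) {
  stopifnot(inherits(outcome, "screen_outcome"))
  status <- rlang::set_names(rep("core", length(outcome$candidates)),
                             outcome$candidates)
  for (m in rev(names(outcome$removed))) {
    status[outcome$removed[[m]]] <- paste0("removed:", m)
  }
  write_csv_safe(tibble(protein = names(status), status = unname(status)), path)
  invisible(path)
}
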