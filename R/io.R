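#' Read an interaction edge list
#'
#' Reads a plain two/three-column edge list into a [ppi_network()]. Lines
#' beginning with `#` are comments, except the directive `# node: LABEL`,
#' which declares an isolated node (this is how [write_edge_list()] preserves
#' degree-zero proteins, keeping write/read round trips exact). An optional
#' third numeric column is treated as a confidence score and ignored for
#' topology: the screen uses the interaction topology only and applies no
#' score threshold.
#'
#' @param path Path to a tab- or whitespace-separated file.
#' @param disease_id Label for the disease the network belongs to.
#' @return A [ppi_network()] with deduplicated undirected edges; self-loops
#'   are dropped with a warning.
#' @export
read_edge_list <- function(path, disease_id = "network") {
  lines <- read_input_lines(path)
  parse_edge_lines(lines, disease_id, path)
}

#' Read a STRING-style interaction export
#'
#' Accepts the tab-separated dialect of STRING network exports: a header row
#' whose first two columns name the interacting proteins (e.g. `node1`,
#' `node2`) followed by numeric score columns. The header is detected and
#' skipped; if the first row already looks like data (its third field, when
#' present, is numeric) the file is treated as a headerless edge list with a
#' logged note. Deduplication rules are those of [read_edge_list()]; rows
#' listing the same pair in both orders collapse to one undirected edge.
#'
#' @inheritParams read_edge_list
#' @return A [ppi_network()].
#' @export
read_string_links <- function(path, disease_id = "network") {
  lines <- read_input_lines(path)
  content <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(content) > 0L) {
    first <- strsplit(trimws(lines[content[1L]]), "[ \t]+")[[1L]]
    looks_header <-
      (length(first) >= 3L && is.na(suppressWarnings(as.numeric(first[3L])))) ||
      (length(first) >= 2L &&
         all(grepl("node|protein|item", tolower(first[1:2]))))
    if (looks_header) {
      lines <- lines[-content[1L]]
    } else {
      inform(sprintf("No header detected in '%s'; reading as plain edge list.",
                     path))
    }
  }
  parse_edge_lines(lines, disease_id, path)
}

read_input_lines <- function(path) {
  check_string(path, "path")
  if (!file.exists(path)) {
    abort_io(sprintf("File not found: '%s'.", path))
  }
  readLines(path, warn = FALSE)
}

parse_edge_lines <- function(lines, disease_id, path) {
  node_directive <- grepl("^#\\s*node:\\s*\\S+", lines)
  declared <- sub("^#\\s*node:\\s*(\\S+).*$", "\\1", lines[node_directive])
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L && length(declared) == 0L) {
    warn(sprintf("'%s' contains no edges; returning an empty network.", path),
         class = "hubscreen_warning")
  }
  tokens <- strsplit(trimws(lines[idx]), "[ \t]+")
  bad <- which(lengths(tokens) < 2L)
  if (length(bad) > 0L) {
    abort_parse(sprintf(
      "Line %d of '%s' has fewer than 2 fields: '%s'.",
      idx[bad[1L]], path, trimws(lines[idx[bad[1L]]])
    ))
  }
  edges <- tibble(
    from = map_chr(tokens, 1L),
    to = map_chr(tokens, 2L)
  )
  ppi_network(edges, nodes = declared, disease_id = disease_id)
}

#' Write a network as an edge list
#'
#' Writes a tab-separated edge list with a comment header; isolated nodes are
#' recorded as `# node: LABEL` directives so that reading the file back
#' reconstructs the node set exactly.
#'
#' @param net A [ppi_network()].
#' @param path Output file path.
#' @param style `"plain"` writes two-column `from<TAB>to` lines;
#'   `"string"` writes a STRING-export-like file with a
#'   `node1 node2 combined_score` header and a constant score column.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(net, path, style = c("plain", "string")) {
  stopifnot(inherits(net, "ppi_network"))
  style <- match.arg(style)
  isolated <- setdiff(net$nodes, unique(c(net$edges$from, net$edges$to)))
  lines <- c(
    sprintf("# disease: %s", net$disease_id),
    sprintf("# node: %s", isolated)
  )
  if (style == "string") {
    lines <- c(lines, "node1\tnode2\tcombined_score",
               sprintf("%s\t%s\t0.900", net$edges$from, net$edges$to))
  } else {
    lines <- c(lines, sprintf("%s\t%s", net$edges$from, net$edges$to))
  }
  write_text_file(lines, path)
  invisible(path)
}

#' Read a regulatory action table
#'
#' Reads a 4-column tab/whitespace-separated table of typed directed
#' regulatory relations: `source`, `target`, `mode`, `directed`. `mode` must
#' be one of `activation`, `inhibition`, `expression`; `directed` is parsed
#' as a logical (`true`/`false`, `1`/`0`, `yes`/`no`). A leading header row
#' naming the columns is skipped if present. Self-relations are rejected.
#'
#' @param path Path to the table.
#' @return A tibble of action edges with columns `source`, `target`, `mode`,
#'   `directed`; zero rows for an empty table (downstream screens then treat
#'   every candidate as isolated).
#' @export
read_action_table <- function(path) {
  lines <- read_input_lines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(tibble(source = character(), target = character(),
                  mode = character(), directed = logical()))
  }
  tokens <- strsplit(trimws(lines[idx]), "[ \t]+")
  first <- tokens[[1L]]
  if (length(first) >= 3L && tolower(first[1L]) == "source" &&
      tolower(first[2L]) == "target") {
    tokens <- tokens[-1L]
    idx <- idx[-1L]
  }
  if (length(tokens) == 0L) {
    return(tibble(source = character(), target = character(),
                  mode = character(), directed = logical()))
  }
  bad <- which(lengths(tokens) < 4L)
  if (length(bad) > 0L) {
    abort_parse(sprintf(
      "Line %d of '%s' has fewer than 4 fields (source, target, mode, directed).",
      idx[bad[1L]], path
    ))
  }
  out <- tibble(
    source = map_chr(tokens, 1L),
    target = map_chr(tokens, 2L),
    mode = tolower(map_chr(tokens, 3L)),
    directed_raw = tolower(map_chr(tokens, 4L))
  )
  unknown <- setdiff(unique(out$mode), action_modes())
  if (length(unknown) > 0L) {
    abort_validation(sprintf(
      "Unknown action mode(s) %s in '%s'; allowed modes are {%s}.",
      paste0("'", unknown, "'", collapse = ", "), path,
      paste(action_modes(), collapse = ", ")
    ))
  }
  truthy <- c("true", "t", "1", "yes")
  falsy <- c("false", "f", "0", "no")
  bad_flag <- !(out$directed_raw %in% c(truthy, falsy))
  if (any(bad_flag)) {
    abort_validation(sprintf(
      "Cannot parse directed flag '%s' (line %d of '%s') as a logical.",
      out$directed_raw[which(bad_flag)[1L]], idx[which(bad_flag)[1L]], path
    ))
  }
  if (any(out$source == out$target)) {
    abort_validation(sprintf(
      "Self-relation '%s' -> itself is not a valid action edge ('%s').",
      out$source[which(out$source == out$target)[1L]], path
    ))
  }
  out |>
    mutate(directed = .data$directed_raw %in% truthy) |>
    select("source", "target", "mode", "directed")
}

#' Write a regulatory action table
#'
#' @param actions A tibble of action edges (see [read_action_table()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_action_table <- function(actions, path) {
  lines <- c(
    "source\ttarget\tmode\tdirected",
    sprintf("%s\t%s\t%s\t%s", actions$source, actions$target, actions$mode,
            tolower(as.character(actions$directed)))
  )
  write_text_file(lines, path)
  invisible(path)
}

#' Write a per-node centrality table
#'
#' Writes a CSV with columns `node`, `degree`, `betweenness`, `closeness`,
#' `stress`, sorted by degree descending then node label ascending.
#' Betweenness and closeness are printed with 3 decimal places (the display
#' convention of network-analysis node tables); use [make_report()] for a
#' parallel full-precision column set.
#'
#' @param records A centrality tibble as returned by [centrality_table()];
#'   must be non-empty.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_node_table <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    abort_validation("`records` must be a non-empty centrality table.")
  }
  out <- records |>
    arrange(desc(.data$degree), .data$node) |>
    mutate(
      betweenness = sprintf("%.3f", .data$betweenness),
      closeness = sprintf("%.3f", .data$closeness),
      stress = format_count(.data$stress)
    ) |>
    select("node", "degree", "betweenness", "closeness", "stress")
  write_csv_safe(out, path)
  invisible(path)
}

write_csv_safe <- function(df, path) {
  tryCatch(
    readr::write_csv(df, path),
    error = function(e) {
      abort_io(sprintf("Cannot write '%s': %s", path, conditionMessage(e)))
    }
  )
  invisible(path)
}

format_count <- function(x) format(round(x), scientific = FALSE, trim = TRUE)

write_text_file <- function(lines, path) {
  ok <- tryCatch({
    con <- file(path, open = "wb")
    on.exit(close(con))
    writeLines(lines, con, sep = "\n")
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    abort_io(sprintf("Cannot write '%s': %s", path, conditionMessage(ok)))
  }
  invisible(path)
}
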