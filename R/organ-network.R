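#' Read a tissue protein list
#'
#' Reads one identifier per line, or a single-column delimited table whose
#' header row is auto-detected (a first line matching a common column name
#' such as `gene`, `protein`, `symbol`, `id` or `name` is treated as a
#' header). Identifiers are canonicalized (upper case, trimmed) and
#' deduplicated; the number of duplicates dropped is reported and attached as
#' the `"n_duplicates"` attribute.
#'
#' @param path Path to the protein list file.
#' @param quiet Suppress the duplicate-count message.
#' @return Character vector of canonical protein identifiers.
#' @export
load_protein_list <- function(path, quiet = FALSE) {
  if (!file.exists(path)) {
    abort(paste0("protein list not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  # tolerate single-column CSV/TSV: strip a trailing delimiter, take field 1
  lines <- vapply(strsplit(lines, "[\t,]"), function(f) {
    if (length(f) == 0) "" else f[[1]]
  }, character(1))
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) abort("no proteins in file")
  header_rx <- "^(gene|genes|protein|proteins|symbol|id|name|identifier)$"
  if (length(lines) > 1 && grepl(header_rx, lines[[1]], ignore.case = TRUE)) {
    lines <- lines[-1]
  }
  ids <- canonicalize_protein(lines)
  out <- unique(ids)
  n_dup <- length(ids) - length(out)
  if (!quiet && n_dup > 0) {
    inform(sprintf("load_protein_list: dropped %d duplicate identifier(s)", n_dup))
  }
  attr(out, "n_duplicates") <- n_dup
  out
}

#' Read and filter an interaction-score table
#'
#' Reads a STRING-links-style table (two identifier columns plus an integer
#' combined score), keeps rows at or above the score cutoff, drops self-pairs
#' after canonicalization, and collapses duplicate unordered pairs keeping
#' the maximum score (STRING exports list each pair in both orientations).
#'
#' @param path Path to a CSV/TSV interaction table (delimiter auto-detected).
#' @param score_cutoff Minimum combined score to keep an edge (inclusive);
#'   default 700, the high-confidence STRING threshold.
#' @param col_a,col_b,col_score Column names in the file.
#' @param quiet Suppress filtering messages.
#' @return Tibble with columns `a`, `b`, `score`; one row per unordered pair.
#' @export
load_interactions <- function(path, score_cutoff = 700,
                              col_a = "protein1", col_b = "protein2",
                              col_score = "combined_score", quiet = FALSE) {
  if (!file.exists(path)) abort(paste0("interaction table not found: ", path))
  tbl <- readr::read_delim(path, show_col_types = FALSE, progress = FALSE)
  missing <- setdiff(c(col_a, col_b, col_score), names(tbl))
  if (length(missing) > 0) {
    abort(paste0("interaction table is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  filter_interactions(
    tibble(a = tbl[[col_a]], b = tbl[[col_b]], score = tbl[[col_score]]),
    score_cutoff = score_cutoff, quiet = quiet
  )
}

#' Filter an in-memory interaction table
#'
#' Same semantics as [load_interactions()] for a data frame already in
#' memory: inclusive score cutoff, self-pair removal, unordered
#' pair deduplication keeping the maximum score.
#'
#' @param interactions Data frame with columns `a`, `b`, `score`.
#' @inheritParams load_interactions
#' @return Tibble with columns `a`, `b`, `score`.
#' @export
filter_interactions <- function(interactions, score_cutoff = 700, quiet = FALSE) {
  stopifnot(all(c("a", "b", "score") %in% names(interactions)))
  tbl <- as_tibble(interactions)
  tbl$a <- canonicalize_protein(tbl$a)
  tbl$b <- canonicalize_protein(tbl$b)
  tbl <- dplyr::filter(tbl, .data$score >= score_cutoff)
  n_self <- sum(tbl$a == tbl$b)
  if (!quiet && n_self > 0) {
    inform(sprintf("filter_interactions: dropped %d self-pair(s)", n_self))
  }
  tbl <- dplyr::filter(tbl, .data$a != .data$b)
  if (nrow(tbl) == 0) {
    return(tibble(a = character(0), b = character(0), score = numeric(0)))
  }
  tbl |>
    dplyr::mutate(
      lo = pmin(.data$a, .data$b),
      hi = pmax(.data$a, .data$b)
    ) |>
    dplyr::summarise(score = max(.data$score), .by = c("lo", "hi")) |>
    dplyr::transmute(a = .data$lo, b = .data$hi, score = .data$score)
}

#' Construct a pruned organ protein network
#'
#' Induces a simple undirected graph on the supplied protein set using only
#' interactions whose both endpoints belong to it, then removes every
#' connected component with fewer than `min_component_size` nodes ("fractions"
#' in the organ-network sense; isolated proteins are size-1 components and
#' are removed whenever `min_component_size > 1`).
#'
#' @param proteins Character vector of protein identifiers (canonicalized
#'   internally), or the output of [load_protein_list()].
#' @param interactions Data frame with columns `a`, `b`, `score` (e.g. from
#'   [load_interactions()]).
#' @param score_cutoff Minimum edge score (inclusive); applied again here so
#'   raw tables can be passed directly.
#' @param min_component_size Smallest connected component retained.
#' @param label Organ label, e.g. `"BSN"` or `"ISN"`.
#' @return An object of class `protein_network` wrapping an igraph graph,
#'   with the build parameters and a report of pruned nodes.
#' @export
#' @examples
#' ints <- tibble::tibble(a = c("A", "B", "C"), b = c("B", "C", "A"),
#'                        score = c(900, 800, 750))
#' net <- build_network(c("A", "B", "C", "D"), ints,
#'                      min_component_size = 3, label = "demo")
#' glance(net)
build_network <- function(proteins, interactions, score_cutoff = 700,
                          min_component_size = 10, label = "organ") {
  stopifnot(score_cutoff >= 0, min_component_size >= 1)
  proteins <- unique(canonicalize_protein(proteins))
  edges <- filter_interactions(interactions, score_cutoff = score_cutoff,
                               quiet = TRUE)
  edges <- dplyr::filter(edges, .data$a %in% proteins, .data$b %in% proteins)
  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = proteins)
  )
  comp <- igraph::components(g)
  keep <- comp$membership %in% which(comp$csize >= min_component_size)
  removed <- igraph::V(g)$name[!keep]
  g <- igraph::induced_subgraph(g, which(keep))
  structure(
    list(
      graph = g,
      label = label,
      params = list(score_cutoff = score_cutoff,
                    min_component_size = min_component_size),
      removed_count = length(removed),
      removed = removed
    ),
    class = "protein_network"
  )
}

#' @export
print.protein_network <- function(x, ...) {
  cat(sprintf(
    "<protein_network '%s'> %d nodes, %d edges (score >= %d, components >= %d; %d node(s) pruned)\n",
    x$label, igraph::vcount(x$graph), igraph::ecount(x$graph),
    x$params$score_cutoff, x$params$min_component_size, x$removed_count
  ))
  invisible(x)
}

#' Network node identifiers
#' @param network A `protein_network`.
#' @return Character vector of node identifiers.
#' @export
network_nodes <- function(network) {
  stopifnot(inherits(network, "protein_network"))
  igraph::V(network$graph)$name
}

#' @describeIn network_nodes Number of nodes.
#' @export
network_size <- function(network) {
  stopifnot(inherits(network, "protein_network"))
  igraph::vcount(network$graph)
}

#' @export
tidy.protein_network <- function(x, ...) {
  g <- x$graph
  comp <- igraph::components(g)
  tibble(
    protein = igraph::V(g)$name,
    degree = as.integer(igraph::degree(g)),
    component = as.integer(comp$membership)
  )
}

#' @export
glance.protein_network <- function(x, ...) {
  tibble(
    label = x$label,
    n_nodes = igraph::vcount(x$graph),
    n_edges = igraph::ecount(x$graph),
    n_components = igraph::components(x$graph)$no,
    n_removed = x$removed_count,
    score_cutoff = x$params$score_cutoff,
    min_component_size = x$params$min_component_size
  )
}

#' Select hub proteins by top degree centrality
#'
#' Hubs are the nodes in the top `hub_fraction` of the degree distribution.
#' With `k = ceiling(hub_fraction * n)` and `d_k` the degree of the k-th node
#' in descending degree order, all nodes tied at `d_k` are included, so
#' membership is exactly `{v : degree(v) > d*}` with integer threshold
#' `d* = d_k - 1`. Tie inclusion can push the hub count slightly above
#' `k` (210 hubs on a 1040-node network at 20%, for instance).
#'
#' @param network A `protein_network`.
#' @param hub_fraction Fraction of nodes taken as hubs, in (0, 1]; default 0.2.
#' @return An object of class `hub_set` with members and the strict degree
#'   threshold `d*`.
#' @export
select_hubs <- function(network, hub_fraction = 0.2) {
  stopifnot(inherits(network, "protein_network"))
  if (!(hub_fraction > 0 && hub_fraction <= 1)) {
    abort("hub_fraction must be in (0, 1]")
  }
  n <- network_size(network)
  if (n == 0) abort("cannot select hubs of an empty network")
  deg <- igraph::degree(network$graph)
  k <- ceiling(hub_fraction * n)
  d_k <- sort(as.integer(deg), decreasing = TRUE)[k]
  members <- names(deg)[deg >= d_k]
  structure(
    list(
      network_ref = network$label,
      members = members,
      hub_fraction = hub_fraction,
      degree_threshold = d_k - 1L
    ),
    class = "hub_set"
  )
}

#' @export
print.hub_set <- function(x, ...) {
  cat(sprintf("<hub_set on '%s'> %d hubs (degree > %d, top %.0f%%)\n",
              x$network_ref, length(x$members), x$degree_threshold,
              100 * x$hub_fraction))
  invisible(x)
}

#' @export
tidy.hub_set <- function(x, ...) {
  tibble(protein = x$members, network = x$network_ref,
         degree_threshold = x$degree_threshold)
}

#' @export
glance.hub_set <- function(x, ...) {
  tibble(network = x$network_ref, n_hubs = length(x$members),
         degree_threshold = x$degree_threshold,
         hub_fraction = x$hub_fraction)
}
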