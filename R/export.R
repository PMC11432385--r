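#' Node-attribute table for network colouring
#'
#' One row per network node with its degree, hub flag, membership in each
#' projected evidence set, DEG regulation direction when a `deg_result` is
#' supplied, and BFS shell index when a `spanning_result` is supplied --
#' the data behind hub/evidence/shell colourings in Cytoscape-style views.
#'
#' @param network A `protein_network`.
#' @param hubs Optional `hub_set`.
#' @param projections Optional named list of `projection`s onto this
#'   network.
#' @param degs Optional `deg_result` for an `regulation` column.
#' @param spanning Optional `spanning_result` for a `shell` column.
#' @return Tibble with one row per node.
#' @export
node_attributes <- function(network, hubs = NULL, projections = NULL,
                            degs = NULL, spanning = NULL) {
  out <- tidy(network)
  if (!is.null(hubs)) {
    out$is_hub <- out$protein %in% hubs$members
  }
  for (nm in names(projections)) {
    out[[paste0("in_", nm)]] <- out$protein %in% projections[[nm]]$mapped
  }
  if (!is.null(degs)) {
    out$regulation <- dplyr::case_when(
      out$protein %in% degs$up ~ "up",
      out$protein %in% degs$down ~ "down",
      .default = "none"
    )
  }
  if (!is.null(spanning)) {
    d <- spanning$distances[out$protein]
    out$shell <- ifelse(is.finite(d), as.integer(d), NA_integer_)
  }
  out
}

#' Export a network as SIF
#'
#' Cytoscape simple-interaction format: `source<TAB>pp<TAB>target`, one
#' line per edge; isolated nodes are listed on their own line.
#'
#' @param network A `protein_network`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_sif <- function(network, path) {
  g <- network$graph
  el <- igraph::as_data_frame(g, what = "edges")
  lines <- sprintf("%s\tpp\t%s", el$from, el$to)
  isolated <- igraph::V(g)$name[igraph::degree(g) == 0]
  writeLines(c(lines, isolated), path)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Degree and (when supplied) hub flag travel as node attributes so the
#' file re-imports into Cytoscape ready for styling.
#'
#' @param network A `protein_network`.
#' @param path Output file.
#' @param hubs Optional `hub_set`.
#' @return Invisibly, `path`.
#' @export
write_graphml <- function(network, path, hubs = NULL) {
  g <- network$graph
  igraph::V(g)$degree <- as.integer(igraph::degree(g))
  if (!is.null(hubs)) {
    igraph::V(g)$is_hub <- as.integer(igraph::V(g)$name %in% hubs$members)
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export all viewer-facing files for one network
#'
#' Writes `network.graphml`, `network.sif` and `node_attributes.tsv` into
#' `dir`.
#'
#' @inheritParams node_attributes
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
export_network_views <- function(network, hubs = NULL, projections = NULL,
                                 degs = NULL, spanning = NULL, dir = ".") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    graphml = file.path(dir, "network.graphml"),
    sif = file.path(dir, "network.sif"),
    attrs = file.path(dir, "node_attributes.tsv")
  )
  write_graphml(network, paths["graphml"], hubs = hubs)
  write_sif(network, paths["sif"])
  readr::write_tsv(
    node_attributes(network, hubs, projections, degs, spanning),
    paths["attrs"], progress = FALSE
  )
  invisible(paths)
}
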