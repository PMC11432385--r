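# Multi-source BFS distances from a seed set, authored frontier-by-frontier
# so shell structure is explicit; tested against igraph's all-pairs
# shortest-path matrix. Returns one distance per node (Inf = unreachable).
seed_distances <- function(network, seeds) {
  g <- network$graph
  nodes <- igraph::V(g)$name
  seeds <- intersect(seeds, nodes)
  if (length(seeds) == 0) abort("no seeds on network")
  adj <- igraph::as_adj_list(g, mode = "all")
  dist <- rep(Inf, length(nodes))
  names(dist) <- nodes
  idx <- match(seeds, nodes)
  dist[idx] <- 0
  frontier <- idx
  k <- 0
  while (length(frontier) > 0) {
    k <- k + 1
    nxt <- unique(unlist(lapply(adj[frontier], as.integer), use.names = FALSE))
    nxt <- nxt[!is.finite(dist[nxt])]
    dist[nxt] <- k
    frontier <- nxt
  }
  dist
}

# Normalise seeds input: evidence_set, projection or character vector.
seed_ids <- function(seeds) {
  if (inherits(seeds, "projection")) return(seeds$mapped)
  if (inherits(seeds, "evidence_set")) return(seeds$members)
  canonicalize_protein(seeds)
}

#' First-shell interaction nodes of a seed set
#'
#' The union of direct neighbours of the seed nodes, excluding the seeds
#' themselves. Seeds not present in the network are dropped (with a message
#' giving the count).
#'
#' @param network A `protein_network`.
#' @param seeds Seed proteins: a character vector, `evidence_set` or
#'   `projection`.
#' @param quiet Suppress the dropped-seed message.
#' @return Character vector of first-shell node identifiers.
#' @export
first_shell <- function(network, seeds, quiet = FALSE) {
  stopifnot(inherits(network, "protein_network"))
  seeds <- seed_ids(seeds)
  nodes <- network_nodes(network)
  n_off <- length(setdiff(seeds, nodes))
  if (!quiet && n_off > 0) {
    inform(sprintf("first_shell: %d seed(s) not on the network dropped", n_off))
  }
  dist <- seed_distances(network, seeds)
  names(dist)[dist == 1]
}

spanning_result <- function(network, seeds, walks) {
  seeds <- intersect(seed_ids(seeds), network_nodes(network))
  dist <- seed_distances(network, seeds)
  n <- length(dist)
  unreachable <- sum(!is.finite(dist))
  reach_max <- max(dist[is.finite(dist)])
  k_max <- if (is.na(walks)) max(1, reach_max) else max(1, walks)
  ks <- 0:k_max
  shells <- tibble(
    walk = as.integer(ks),
    covered = vapply(ks, function(k) sum(dist <= k), 0L),
    rate = vapply(ks, function(k) sum(dist <= k), 0L) / n
  )
  shells$percent <- format_percent(shells$rate)
  structure(
    list(
      network_ref = network$label,
      seed_size = length(seeds),
      n_nodes = n,
      shells = shells,
      walks_to_full = as.integer(reach_max),
      unreachable_count = as.integer(unreachable),
      distances = dist
    ),
    class = "spanning_result"
  )
}

#' Network-dimension spanning rate of a seed set
#'
#' Treats each network node as one dimension of the organ's functional
#' space and measures how much of it lies within `walks` BFS layers of the
#' seed set: `covered(k) = #{v : d(v, seeds) <= k}` with unweighted hop
#' distances. `walk = 0` is the seeds themselves; `walk = 1` adds the first
#' shell. Rates are reported as percentages rounded half-up to two decimals
#' (698 of 1040 nodes prints as "67.12%").
#'
#' @param network A `protein_network`.
#' @param seeds Seed proteins: character vector, `evidence_set` or
#'   `projection`. Seeds off the network are dropped.
#' @param walks Number of BFS layers to report (>= 0).
#' @return An object of class `spanning_result`; `$shells` is a tibble with
#'   columns `walk`, `covered`, `rate`, `percent`.
#' @export
spanning_rate <- function(network, seeds, walks = 1) {
  stopifnot(inherits(network, "protein_network"), walks >= 0)
  res <- spanning_result(network, seeds, walks = walks)
  res$shells <- res$shells[res$shells$walk <= max(walks, 1), ]
  res
}

#' Walks to full network spanning
#'
#' Expands breadth-first from the seed set until no new node is reached.
#' `walks_to_full` is the eccentricity of the seed set over reachable nodes:
#' the smallest `k` at which every reachable node lies within `k` hops.
#' Nodes in components containing no seed can never be covered; they are
#' counted in `unreachable_count` and excluded from "full".
#'
#' @inheritParams spanning_rate
#' @return A `spanning_result` with shells reported through `walks_to_full`.
#' @export
walks_to_full_span <- function(network, seeds) {
  stopifnot(inherits(network, "protein_network"))
  spanning_result(network, seeds, walks = NA)
}

#' @export
print.spanning_result <- function(x, ...) {
  k1 <- x$shells[x$shells$walk == 1, ]
  cat(sprintf(
    "<spanning_result on '%s'> %d seeds; shell-1 coverage %s; full span in %d walk(s)%s\n",
    x$network_ref, x$seed_size, k1$percent, x$walks_to_full,
    if (x$unreachable_count > 0) {
      sprintf(" (%d unreachable node(s) excluded)", x$unreachable_count)
    } else ""
  ))
  invisible(x)
}

#' @export
tidy.spanning_result <- function(x, ...) x$shells

#' @export
glance.spanning_result <- function(x, ...) {
  k1 <- x$shells[x$shells$walk == 1, ]
  tibble(
    network = x$network_ref,
    seed_size = x$seed_size,
    n_nodes = x$n_nodes,
    covered_shell1 = k1$covered,
    rate_shell1 = k1$rate,
    percent_shell1 = k1$percent,
    walks_to_full = x$walks_to_full,
    unreachable = x$unreachable_count
  )
}

#' Plot methods for spanning and permutation results
#'
#' `autoplot.spanning_result` draws the coverage curve (fraction of network
#' dimensions covered per BFS walk).
#'
#' @param object A `spanning_result` or `permutation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.spanning_result <- function(object, ...) {
  ggplot2::ggplot(object$shells,
                  ggplot2::aes(x = .data$walk, y = 100 * .data$rate)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$shells$walk) +
    ggplot2::labs(
      x = "walk (BFS layer)", y = "network dimensions covered (%)",
      title = sprintf("Spanning of '%s' from %d seeds",
                      object$network_ref, object$seed_size)
    ) +
    ggplot2::theme_minimal()
}
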