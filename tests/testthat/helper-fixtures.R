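# Small graph builders used across the suite. All edges get a score of 900
# (above the default cutoff) unless stated otherwise.

edges_tbl <- function(a, b, score = 900) {
  tibble::tibble(a = a, b = b, score = score)
}

# A simple path a-b-c-... over the given node names.
path_net <- function(nodes, label = "path") {
  n <- length(nodes)
  build_network(nodes, edges_tbl(nodes[-n], nodes[-1]),
                min_component_size = 1, label = label)
}

# n-node cycle.
cycle_net <- function(nodes, label = "cycle") {
  n <- length(nodes)
  build_network(nodes, edges_tbl(nodes, nodes[c(2:n, 1)]),
                min_component_size = 1, label = label)
}

# Network from an explicit igraph graph (all scores 900).
net_from_igraph <- function(g, label = "g", min_component_size = 1) {
  el <- igraph::as_data_frame(g, what = "edges")
  build_network(igraph::V(g)$name, edges_tbl(el$from, el$to),
                min_component_size = min_component_size, label = label)
}

# Hub-and-leaf construction with exact hub counts under the top-fraction
# tie-inclusive rule: `n_hubs` nodes form a cycle, the remaining
# `n_nodes - n_hubs` nodes attach as leaves distributed round-robin, so hub
# degrees (5 or 6) dominate leaf degrees (1) and select_hubs() at 20%
# returns exactly the intended hub block.
hub_leaf_net <- function(n_nodes, n_hubs, label = "hl") {
  hubs <- sprintf("H%04d", seq_len(n_hubs))
  leaves <- sprintf("L%04d", seq_len(n_nodes - n_hubs))
  cyc <- edges_tbl(hubs, hubs[c(2:n_hubs, 1)])
  att <- edges_tbl(leaves, hubs[(seq_along(leaves) - 1) %% n_hubs + 1])
  net <- build_network(c(hubs, leaves), dplyr::bind_rows(cyc, att),
                       min_component_size = 10, label = label)
  list(net = net, hubs = hubs, leaves = leaves)
}

# Random connected-ish Erdos-Renyi style synthetic graph for property tests.
random_net <- function(n = 50, p = 0.08, seed = 1, label = "rand") {
  withr::with_seed(seed, {
    g <- igraph::sample_gnp(n, p)
    igraph::V(g)$name <- sprintf("N%03d", seq_len(n))
    net_from_igraph(g, label = label)
  })
}

# Exhaustive hypergeometric tail by enumerating all samples of size m.
enumerated_tail <- function(nodes, hubs, m, observed) {
  combos <- utils::combn(nodes, m)
  hits <- colSums(matrix(combos %in% hubs, nrow = m))
  mean(hits >= observed)
}
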