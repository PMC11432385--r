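test_that("generators are pure functions of the configuration", {
  cfg <- synthetic_config(n_proteins = 120, seed = 6,
                          decoy_clique_sizes = c(4, 4))
  a <- generate_network(cfg)
  b <- generate_network(cfg)
  expect_identical(a, b)
  expect_identical(generate_de_table(cfg), generate_de_table(cfg))
  expect_identical(generate_docking_table(cfg, a$proteins[1:50]),
                   generate_docking_table(cfg, a$proteins[1:50]))
})

test_that("generated graphs satisfy the handshake lemma and score bookkeeping", {
  cfg <- synthetic_config(n_proteins = 150, seed = 2)
  raw <- generate_network(cfg)
  g <- igraph::graph_from_data_frame(raw$interactions[, 1:2],
                                     directed = FALSE)
  expect_equal(sum(igraph::degree(g)), 2 * nrow(raw$interactions))
  expect_equal(raw$truth$n_edges_above_cutoff +
                 raw$truth$n_edges_below_cutoff,
               nrow(raw$interactions))
  expect_equal(sum(raw$interactions$score >= 700),
               raw$truth$n_edges_above_cutoff)
})

test_that("decoy cliques are pruned in full; forced-high scores keep every row", {
  cfg <- synthetic_config(n_proteins = 200, seed = 10,
                          decoy_clique_sizes = c(4, 4, 4))
  raw <- generate_network(cfg)
  net <- build_network(raw$proteins, raw$interactions,
                       min_component_size = 10)
  expect_true(all(raw$truth$clique_nodes %in% net$removed))
  expect_length(intersect(raw$truth$clique_nodes, network_nodes(net)), 0)

  all_high <- synthetic_config(n_proteins = 100, below_cutoff_frac = 0,
                               seed = 11)
  raw2 <- generate_network(all_high)
  kept <- filter_interactions(raw2$interactions, score_cutoff = 700)
  expect_equal(nrow(kept), nrow(raw2$interactions))
})

test_that("hub-bias extremes behave as planted", {
  cfg <- synthetic_config(n_proteins = 150, seed = 14)
  raw <- generate_network(cfg)
  net <- build_network(raw$proteins, raw$interactions, min_component_size = 10)
  hubs <- select_hubs(net)
  all_hub <- generate_evidence(net, hubs,
                               evidence_size = length(hubs$members) - 2,
                               hub_bias = 1, seed = 4)
  expect_true(all(all_hub$members %in% hubs$members))
  e1 <- generate_evidence(net, hubs, evidence_size = 20, hub_bias = 0.5,
                          seed = 4)
  e2 <- generate_evidence(net, hubs, evidence_size = 20, hub_bias = 0.5,
                          seed = 4)
  expect_identical(e1$members, e2$members)
})

test_that("bundles round-trip through the plain-text writers and readers", {
  cfg <- synthetic_config(n_proteins = 80, n_genes = 200, planted_up = 10,
                          planted_down = 5, n_compounds = 20, planted_dp = 3,
                          seed = 9)
  bundle <- simulate_bundle(cfg, label = "ORG")
  dir <- withr::local_tempdir()
  write_bundle(bundle, dir)
  back <- read_bundle(dir, label = "ORG")
  expect_setequal(back$proteins, canonicalize_protein(bundle$proteins))
  expect_equal(nrow(back$interactions), nrow(bundle$interactions))
  expect_equal(back$np_targets, bundle$np_targets,  ignore_attr = TRUE)
  expect_equal(back$docking, bundle$docking, ignore_attr = TRUE)
  expect_equal(back$de, bundle$de, ignore_attr = TRUE)
})

test_that("the planted evidence of a bundle is recoverable end to end", {
  cfg <- synthetic_config(n_proteins = 150, n_genes = 400, planted_up = 20,
                          planted_down = 10, n_compounds = 40, planted_dp = 5,
                          evidence_size = 30, hub_bias = 0.5, seed = 23)
  bundle <- simulate_bundle(cfg, label = "ORG")
  np <- parse_np_targets(bundle$np_targets)
  expect_setequal(np$members, bundle$truth$np$planted)
  dp <- select_dockable_proteins(filter_valid_interactions(bundle$docking))
  expect_true(all(bundle$truth$dp$planted %in% dp$members))
  degs <- select_degs(bundle$de)
  expect_setequal(degs$up, bundle$truth$deg$up)
  expect_setequal(degs$down, bundle$truth$deg$down)
})
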