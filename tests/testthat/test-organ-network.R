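test_that("protein lists are canonicalized, deduplicated and header-tolerant", {
  f <- withr::local_tempfile(lines = c("chrm1", "CHRM1", "RPE65"))
  ids <- suppressMessages(load_protein_list(f))
  expect_setequal(ids, c("CHRM1", "RPE65"))
  expect_identical(attr(ids, "n_duplicates"), 1L)

  f2 <- withr::local_tempfile(lines = c("gene", "A", "B", "C", "D", "E"))
  expect_length(load_protein_list(f2, quiet = TRUE), 5)

  f3 <- withr::local_tempfile(lines = character(0))
  expect_error(load_protein_list(f3), "no proteins")
  expect_error(load_protein_list(file.path(tempdir(), "absent.txt")),
               "not found")
})

test_that("interaction filtering applies inclusive cutoff, drops self-pairs, dedups unordered", {
  tbl <- edges_tbl(c("A", "B", "C"), c("B", "C", "C"), c(700, 699, 950))
  out <- suppressMessages(filter_interactions(tbl, score_cutoff = 700))
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 700)
  expect_setequal(c(out$a, out$b), c("A", "B"))

  dup <- edges_tbl(c("A", "B"), c("B", "A"), c(800, 750))
  out2 <- filter_interactions(dup, score_cutoff = 700)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$score, 800)
})

test_that("interaction reader reports missing columns by name", {
  f <- withr::local_tempfile(lines = c("protein1\tprotein2\tweird",
                                       "A\tB\t900"))
  expect_error(load_interactions(f), "combined_score")
})

test_that("build_network induces, prunes small components, and reports removals", {
  # all isolated: everything below the component floor vanishes
  empty <- build_network(sprintf("P%02d", 1:15), edges_tbl(character(0),
                         character(0), numeric(0)), min_component_size = 10)
  expect_equal(network_size(empty), 0)
  expect_equal(empty$removed_count, 15)

  # 12-cycle survives, disjoint triangle does not
  cyc <- sprintf("C%02d", 1:12)
  tri <- c("T1", "T2", "T3")
  ints <- dplyr::bind_rows(
    edges_tbl(cyc, cyc[c(2:12, 1)]),
    edges_tbl(tri, tri[c(2, 3, 1)])
  )
  net <- build_network(c(cyc, tri), ints, min_component_size = 10)
  expect_equal(network_size(net), 12)
  expect_equal(igraph::ecount(net$graph), 12)
  expect_setequal(net$removed, tri)

  # interactions with endpoints outside the protein list are ignored
  net2 <- build_network(cyc, ints, min_component_size = 10)
  expect_equal(network_size(net2), 12)
})

test_that("build_network is idempotent and monotone in the score cutoff", {
  withr::with_seed(11, {
    g <- igraph::sample_gnp(40, 0.1)
    igraph::V(g)$name <- sprintf("N%02d", 1:40)
    el <- igraph::as_data_frame(g, what = "edges")
    ints <- edges_tbl(el$from, el$to, sample(400:1000, nrow(el), TRUE))
  })
  prots <- sprintf("N%02d", 1:40)
  net <- build_network(prots, ints, score_cutoff = 700,
                       min_component_size = 3)
  # idempotence: rebuild from own output
  own_edges <- igraph::as_data_frame(net$graph, what = "edges")
  net2 <- build_network(network_nodes(net),
                        edges_tbl(own_edges$from, own_edges$to, 900),
                        score_cutoff = 700, min_component_size = 3)
  expect_setequal(network_nodes(net2), network_nodes(net))
  expect_equal(igraph::ecount(net2$graph), igraph::ecount(net$graph))
  # cutoff monotonicity
  sizes <- purrr::map(c(500, 700, 900), function(cut) {
    n <- build_network(prots, ints, score_cutoff = cut,
                       min_component_size = 3)
    c(network_size(n), igraph::ecount(n$graph))
  })
  expect_true(all(diff(purrr::map_dbl(sizes, 1)) <= 0))
  expect_true(all(diff(purrr::map_dbl(sizes, 2)) <= 0))
})

test_that("every retained component meets the size floor on random networks", {
  for (s in 1:200) {
    cfg <- synthetic_config(n_proteins = 60, seed = s,
                            decoy_clique_sizes = c(3, 5))
    raw <- generate_network(cfg)
    net <- build_network(raw$proteins, raw$interactions,
                         min_component_size = 10)
    if (network_size(net) == 0) next
    expect_gte(min(igraph::components(net$graph)$csize), 10)
    # handshake lemma on the built graph
    expect_equal(sum(igraph::degree(net$graph)),
                 2 * igraph::ecount(net$graph))
  }
})

test_that("hub selection cuts at the k-th degree with ties included", {
  # degree sequence [7,5,4,3,2,2,2,1,1,1]: k = 2, cut degree 5
  g <- igraph::realize_degseq(c(7, 5, 4, 3, 2, 2, 2, 1, 1, 1))
  igraph::V(g)$name <- sprintf("V%02d", 1:10)
  net <- net_from_igraph(g)
  hubs <- select_hubs(net, hub_fraction = 0.2)
  deg <- igraph::degree(net$graph)
  expect_length(hubs$members, 2)
  expect_setequal(as.integer(deg[hubs$members]), c(7, 5))
  expect_identical(hubs$degree_threshold, 4L)

  # fraction 1 makes everything a hub
  all_hubs <- select_hubs(net, hub_fraction = 1)
  expect_setequal(all_hubs$members, network_nodes(net))
  expect_identical(all_hubs$degree_threshold, as.integer(min(deg) - 1))

  expect_error(select_hubs(net, hub_fraction = 0), "hub_fraction")
  expect_error(select_hubs(net, hub_fraction = 1.2), "hub_fraction")
})

test_that("hub membership equals the strict-threshold form on random graphs", {
  for (s in 1:25) {
    net <- random_net(n = 40, p = 0.12, seed = s)
    if (network_size(net) < 5) next
    hubs <- select_hubs(net, hub_fraction = 0.2)
    deg <- igraph::degree(net$graph)
    strict <- names(deg)[deg > hubs$degree_threshold]
    expect_setequal(hubs$members, strict)
    expect_gte(length(hubs$members), ceiling(0.2 * network_size(net)))
  }
})

test_that("tie inclusion can push the hub count above the nominal fraction", {
  # 210 of 1040 at 20% (nominal 208), as in a tissue network with tied cut degree
  hl <- hub_leaf_net(1040, 210)
  hubs <- select_hubs(hl$net, hub_fraction = 0.2)
  expect_length(hubs$members, 210)
  expect_setequal(hubs$members, hl$hubs)
})
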