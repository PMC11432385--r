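test_that("first shell is the neighbour union minus the seeds", {
  net <- path_net(c("a", "b", "c", "d", "e"))
  expect_setequal(first_shell(net, "c"), c("B", "D"))
  expect_length(first_shell(net, network_nodes(net)), 0)
  expect_message(first_shell(net, c("c", "zz")), "1 seed")
  expect_error(first_shell(net, "zz"), "no seeds")
})

test_that("first shell matches a brute-force edge scan on random graphs", {
  withr::with_seed(12, {
    for (i in 1:10) {
      net <- random_net(n = 50, p = 0.08, seed = i * 7)
      nodes <- network_nodes(net)
      seeds <- sample(nodes, 5)
      el <- igraph::as_data_frame(net$graph, what = "edges")
      touching <- c(el$to[el$from %in% seeds], el$from[el$to %in% seeds])
      expect_setequal(first_shell(net, seeds, quiet = TRUE),
                      setdiff(unique(touching), seeds))
    }
  })
})

test_that("spanning rates come from BFS layer counts with report rounding", {
  net <- path_net(c("a", "b", "c", "d", "e"))
  res <- spanning_rate(net, "c", walks = 1)
  k1 <- res$shells[res$shells$walk == 1, ]
  expect_equal(k1$covered, 3)
  expect_identical(k1$percent, "60.00%")
  expect_equal(res$shells$covered[res$shells$walk == 0], 1)

  full <- spanning_rate(net, network_nodes(net), walks = 3)
  expect_true(all(full$shells$covered == 5))
  expect_true(all(full$shells$percent == "100.00%"))
})

test_that("walks to full span is the seed-set eccentricity", {
  net <- path_net(c("a", "b", "c", "d", "e"))
  expect_equal(walks_to_full_span(net, "a")$walks_to_full, 4)
  expect_equal(walks_to_full_span(net, network_nodes(net))$walks_to_full, 0)
})

test_that("components without seeds are reported unreachable, not looped over", {
  nodes <- c(letters[1:5], paste0("z", 1:3))
  ints <- dplyr::bind_rows(
    edges_tbl(letters[1:4], letters[2:5]),
    edges_tbl(paste0("z", 1:2), paste0("z", 2:3))
  )
  net <- build_network(nodes, ints, min_component_size = 1)
  res <- walks_to_full_span(net, "a")
  expect_equal(res$unreachable_count, 3)
  expect_equal(res$walks_to_full, 4)
  expect_lt(max(res$shells$rate), 1)
})

test_that("shells equal an all-pairs-shortest-path thresholding oracle", {
  for (i in 1:30) {
    net <- random_net(n = 50, p = 0.07, seed = 100 + i)
    nodes <- network_nodes(net)
    seeds <- withr::with_seed(i, sample(nodes, sample(2:6, 1)))
    res <- walks_to_full_span(net, seeds)
    d <- igraph::distances(net$graph, v = seeds)
    dmin <- apply(d, 2, min)
    for (k in res$shells$walk) {
      expect_equal(res$shells$covered[res$shells$walk == k],
                   sum(dmin <= k))
    }
    expect_equal(res$walks_to_full, max(dmin[is.finite(dmin)]))
    expect_equal(res$unreachable_count, sum(!is.finite(dmin)))
  }
})

test_that("coverage is monotone and consistent with the first shell", {
  for (i in 1:10) {
    net <- random_net(n = 40, p = 0.1, seed = 200 + i)
    seeds <- withr::with_seed(i, sample(network_nodes(net), 4))
    res <- walks_to_full_span(net, seeds)
    expect_true(all(diff(res$shells$covered) >= 0))
    expect_equal(res$shells$covered[res$shells$walk == 0], 4)
    expect_equal(res$shells$covered[res$shells$walk == 1],
                 4 + length(first_shell(net, seeds, quiet = TRUE)))
  }
})

test_that("adding a seed never slows spanning", {
  withr::with_seed(33, {
    for (i in 1:8) {
      net <- random_net(n = 40, p = 0.1, seed = 300 + i)
      nodes <- network_nodes(net)
      seeds <- sample(nodes, 3)
      extra <- sample(setdiff(nodes, seeds), 1)
      base <- walks_to_full_span(net, seeds)
      more <- walks_to_full_span(net, c(seeds, extra))
      expect_lte(more$walks_to_full, base$walks_to_full)
      ks <- intersect(base$shells$walk, more$shells$walk)
      expect_true(all(
        more$shells$covered[match(ks, more$shells$walk)] >=
          base$shells$covered[match(ks, base$shells$walk)]
      ))
    }
  })
})
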