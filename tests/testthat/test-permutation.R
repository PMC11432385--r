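test_that("exact tail probability matches exhaustive enumeration", {
  # 10 nodes, 2 hubs, samples of 3: enumerate all C(10,3) = 120 samples
  nodes <- sprintf("N%02d", 1:10)
  hubs <- nodes[1:2]
  expect_equal(enumerated_tail(nodes, hubs, 3, 1), 8 / 15)
  expect_equal(exact_pvalue(10, 2, 3, 1), 8 / 15)

  # 6 nodes, 3 hubs, sample 3, all hubs: C(3,3)/C(6,3) = 1/20
  nodes6 <- sprintf("M%d", 1:6)
  expect_equal(enumerated_tail(nodes6, nodes6[1:3], 3, 3), 1 / 20)
  expect_equal(exact_pvalue(6, 3, 3, 3), 0.05)

  expect_equal(exact_pvalue(50, 10, 5, 0), 1)
  expect_error(exact_pvalue(10, 12, 3, 1), "inconsistent")
  expect_error(exact_pvalue(10, 2, 3, 3), "inconsistent")
})

perm_fixture <- function(n_nodes = 30, n_hubs = 6, ev_ids, seed_net = 1) {
  hl <- hub_leaf_net(n_nodes, n_hubs)
  hubs <- select_hubs(hl$net)
  pr <- project_evidence(evidence_set(ev_ids(hl), "NP"), hl$net)
  list(net = hl$net, hubs = hubs, pr = pr, hl = hl)
}

test_that("permutation estimate tracks the exact hypergeometric tail", {
  fx <- perm_fixture(30, 6, function(hl) c(hl$hubs[1:2], hl$leaves[1:4]))
  res <- permutation_pvalue(fx$net, fx$hubs, fx$pr, n_permutations = 20000,
                            seed = 101)
  p_exact <- exact_pvalue(30, length(fx$hubs$members), 6,
                          res$observed_hub_hits)
  se <- sqrt(p_exact * (1 - p_exact) / 20000)
  expect_lt(abs(res$p_value - p_exact), 3 * se)
  expect_equal(res$observed_hub_hits, 2)
  expect_equal(res$sample_size, 6)
})

test_that("observed count of zero gives p = 1", {
  fx <- perm_fixture(30, 6, function(hl) hl$leaves[1:5])
  res <- permutation_pvalue(fx$net, fx$hubs, fx$pr, n_permutations = 500,
                            seed = 1)
  expect_equal(res$p_value, 1)
})

test_that("identical inputs and seed give bit-identical results", {
  fx <- perm_fixture(40, 8, function(hl) c(hl$hubs[1:3], hl$leaves[1:7]))
  r1 <- permutation_pvalue(fx$net, fx$hubs, fx$pr, n_permutations = 2000,
                           seed = 77)
  r2 <- permutation_pvalue(fx$net, fx$hubs, fx$pr, n_permutations = 2000,
                           seed = 77)
  expect_identical(r1, r2)
  r3 <- permutation_pvalue(fx$net, fx$hubs, fx$pr, n_permutations = 2000,
                           seed = 78)
  expect_false(identical(r1$null_counts, r3$null_counts))
})

test_that("zero exceedances display as the <1/N form and p_plus_one never hits zero", {
  hl <- hub_leaf_net(200, 40)
  hubs <- select_hubs(hl$net)
  pr <- project_evidence(evidence_set(hl$hubs[1:30], "NP"), hl$net)
  res <- permutation_pvalue(hl$net, hubs, pr, n_permutations = 1000, seed = 5)
  expect_equal(res$p_value, 0)
  expect_identical(res$p_display, "<0.001")
  expect_equal(res$p_plus_one, 1 / 1001)
})

test_that("count and ratio statistics are rank-equivalent at fixed sample size", {
  fx <- perm_fixture(30, 6, function(hl) c(hl$hubs[1:2], hl$leaves[1:4]))
  res <- permutation_pvalue(fx$net, fx$hubs, fx$pr, n_permutations = 5000,
                            seed = 3)
  counts <- res$null_counts
  m <- res$sample_size
  h <- length(fx$hubs$members)
  obs <- res$observed_hub_hits
  expect_equal(mean(counts / m >= obs / m), res$p_value)
  expect_equal(mean(counts / h >= obs / h), res$p_value)
})

test_that("strict-tail option and precondition errors behave", {
  fx <- perm_fixture(30, 6, function(hl) c(hl$hubs[1:2], hl$leaves[1:4]))
  geq <- permutation_pvalue(fx$net, fx$hubs, fx$pr, n_permutations = 3000,
                            seed = 9, tail = "geq")
  gt <- permutation_pvalue(fx$net, fx$hubs, fx$pr, n_permutations = 3000,
                           seed = 9, tail = "gt")
  expect_lte(gt$p_value, geq$p_value)
  expect_error(permutation_pvalue(fx$net, fx$hubs, fx$pr,
                                  n_permutations = 0), "n_permutations")
  empty_pr <- project_evidence(evidence_set("ZZ", "NP"), fx$net)
  expect_error(permutation_pvalue(fx$net, fx$hubs, empty_pr,
                                  n_permutations = 10), "no mapped")
})
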