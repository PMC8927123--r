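test_that("jaccard index matches hand-enumerated pair counts", {
  p <- node_partition(c(1, 1, 2, 2))
  self <- jaccard_index(p, p)
  expect_equal(self$jaccard, 1.0)
  # {1,2},{3,4} vs {1,2,3},{4}: 6 pairs, n11 = 1, n10 = 1, n01 = 2
  q <- node_partition(c(1, 1, 1, 2))
  j <- jaccard_index(p, q)
  expect_equal(j$n11, 1); expect_equal(j$n10, 1); expect_equal(j$n01, 2)
  expect_equal(j$n00, 2)
  expect_equal(j$jaccard, 0.25)
  # all-singletons vs single cluster: no co-assigned pairs at all
  expect_equal(jaccard_index(node_partition(1:5),
                             node_partition(rep(1, 5)))$jaccard, 0)
  expect_error(jaccard_index(p, node_partition(c(1, 2))), "different")
})

test_that("jaccard is symmetric and relabeling-invariant", {
  set.seed(12)
  for (trial in 1:100) {
    n <- sample(5:12, 1)
    p1 <- random_partition(n, sample(2:4, 1))
    p2 <- random_partition(n, sample(2:4, 1))
    j12 <- jaccard_index(p1, p2)
    j21 <- jaccard_index(p2, p1)
    expect_equal(j12$jaccard, j21$jaccard)
    expect_equal(j12$n10, j21$n01)
    expect_equal(j12$n11 + j12$n10 + j12$n01 + j12$n00, choose(n, 2))
    # relabel p2's clusters arbitrarily: same similarity
    relab <- sample(p2$k)[p2$assignment]
    expect_equal(jaccard_index(p1, node_partition(relab))$jaccard,
                 j12$jaccard)
    expect_equal(jaccard_index(p1, p1)$jaccard, 1.0)
  }
})

test_that("trajectory clustering recovers equitable clusters at k = k*", {
  g <- planted_study_network(seed = 1, sizes = small_sizes)
  traj <- consensus_trajectories(g$network)
  bench <- trajectory_benchmark_partition(traj, 5, seed = 3)
  expect_partition_equal(bench, g$partition)
  # identical trajectories everywhere: any k attains objective 0
  flat <- structure(list(times = 1:10, states = matrix(1, 6, 10),
                         component = NULL), class = "trajectory_set")
  p <- trajectory_benchmark_partition(flat, 3, seed = 1)
  expect_equal(p$k, 3)
  # seed determinism
  pert <- perturb(g$network, 0.2, "type1", seed = 5)
  traj2 <- consensus_trajectories(pert)
  b1 <- trajectory_benchmark_partition(traj2, 4, seed = 9)
  b2 <- trajectory_benchmark_partition(traj2, 4, seed = 9)
  expect_identical(b1$assignment, b2$assignment)
})

test_that("greedy modularity finds two planted dense blocks", {
  # two dense blocks, weak coupling; exhaustive bipartition search is
  # the modularity oracle
  set.seed(14)
  n <- 10
  a <- matrix(0.01, n, n)
  a[1:5, 1:5] <- 1
  a[6:10, 6:10] <- 1
  diag(a) <- 0
  hier <- community_structure_hierarchy(a)
  got <- hier[["2"]]
  truth <- node_partition(rep(1:2, each = 5))
  expect_partition_equal(got, truth)
  # oracle: best modularity over all 2^(n-1)-1 bipartitions
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE)
  best_q <- -Inf; best_split <- NULL
  for (code in 1:(2^(n - 1) - 1)) {
    memb <- as.integer(intToBits(code))[1:n] + 1L
    if (length(unique(memb)) < 2) next
    q <- igraph::modularity(g, memb, weights = igraph::E(g)$weight)
    if (q > best_q) { best_q <- q; best_split <- memb }
  }
  expect_partition_equal(node_partition(best_split), truth)
})

test_that("dendrogram cuts have k clusters; k = N-1 merges one pair", {
  g <- planted_study_network(seed = 2, sizes = c(4, 3, 5))
  sym <- (g$network$weights + t(g$network$weights)) / 2
  hier <- community_structure_hierarchy(sym)
  for (k in 2:11) {
    expect_equal(hier[[as.character(k)]]$k, k)
  }
  expect_equal(sort(tabulate(hier[["11"]]$assignment)),
               c(rep(1, 10), 2))
})

test_that("asymmetric and negative weights are handled with warnings", {
  set.seed(15)
  a <- matrix(stats::rexp(64), 8, 8); diag(a) <- 0
  expect_warning(community_structure_hierarchy(a), "symmetrized")
  b <- (a + t(a)) / 2
  b[1, 2] <- b[2, 1] <- -0.5
  expect_warning(community_structure_hierarchy(b), "clamped")
})

test_that("compare_methods scores the exact network perfectly at k*", {
  g <- planted_study_network(seed = 1, sizes = c(4, 3, 5))
  suppressWarnings(cmp <- compare_methods(g$network, k_max = 6, seed = 8))
  expect_equal(cmp$k, 2:6)
  expect_true(all(cmp$j_dyncomm >= 0 & cmp$j_dyncomm <= 1, na.rm = TRUE))
  expect_true(all(cmp$j_community >= 0 & cmp$j_community <= 1, na.rm = TRUE))
  expect_equal(cmp$j_dyncomm[cmp$k == 3], 1.0)
})
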