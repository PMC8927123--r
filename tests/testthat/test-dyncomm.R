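test_that("dissimilarities equal brute-force pairwise Euclidean norms", {
  expect_equal(dissimilarity_matrix(matrix(1, 4, 2)), matrix(0, 4, 4))
  p <- rbind(c(3, 0), c(0, 4))
  expect_equal(dissimilarity_matrix(p), matrix(c(0, 5, 5, 0), 2, 2))
  set.seed(13)
  p6 <- matrix(stats::rnorm(12), 6, 2)
  d <- dissimilarity_matrix(p6)
  brute <- matrix(0, 6, 6)
  for (i in 1:6) for (j in 1:6) {
    brute[i, j] <- sqrt(sum((p6[i, ] - p6[j, ])^2))
  }
  expect_equal(d, brute)
  expect_equal(d, t(d))
  expect_equal(diag(d), rep(0, 6))
})

test_that("k-medoids separates well-separated groups on every run", {
  # two groups with >= 10x separation: exhaustive medoid-pair search
  # confirms the optimum is the true 2-group split
  set.seed(17)
  p <- rbind(matrix(stats::rnorm(10, 0, 0.05), 5, 2),
             matrix(stats::rnorm(10, 10, 0.05), 5, 2))
  d <- dissimilarity_matrix(p)
  truth <- node_partition(rep(1:2, each = 5))
  best_obj <- Inf; best_pair <- NULL
  for (m1 in 1:9) for (m2 in (m1 + 1):10) {
    obj <- mean(pmin(d[, m1], d[, m2]))
    if (obj < best_obj) { best_obj <- obj; best_pair <- c(m1, m2) }
  }
  expect_length(unique(truth$assignment[best_pair]), 2L)
  for (trial in 1:10) {
    got <- kmedoids(d, 2, n_restarts = 1, seed = trial)
    expect_partition_equal(got, truth)
    expect_equal(attr(got, "objective"), best_obj)
  }
})

test_that("k = N-1 pairs up the closest two points (exhaustive check)", {
  set.seed(23)
  for (trial in 1:5) {
    p <- matrix(stats::rnorm(14), 7, 2)
    d <- dissimilarity_matrix(p)
    got <- kmedoids(d, 6, n_restarts = 30, seed = trial)
    sizes <- tabulate(got$assignment, 6)
    expect_equal(sort(sizes), c(1, 1, 1, 1, 1, 2))
    pair <- which(got$assignment == which(sizes == 2))
    off <- d[upper.tri(d)]
    expect_equal(d[pair[1], pair[2]], min(off))
  }
})

test_that("degenerate all-zero dissimilarities yield objective 0", {
  d <- matrix(0, 6, 6)
  got <- kmedoids(d, 2, n_restarts = 3, seed = 1)
  expect_equal(attr(got, "objective"), 0)
  expect_equal(got$k, 2)
})

test_that("k-medoids validates k and is seed-deterministic", {
  d <- dissimilarity_matrix(matrix(stats::rnorm(10), 5, 2))
  expect_error(kmedoids(d, 1), "2..N-1")
  expect_error(kmedoids(d, 5), "2..N-1")
  expect_identical(kmedoids(d, 3, seed = 4)$assignment,
                   kmedoids(d, 3, seed = 4)$assignment)
})

test_that("the sweep records one partition with exactly k clusters per k", {
  g <- planted_study_network(seed = 2, sizes = c(4, 3, 5))
  pert <- perturb(g$network, 0.05, "type1", seed = 3)
  sw <- dynamical_communities_sweep(pert, seed = 6)
  expect_equal(sw$ks, 2:11)
  for (k in sw$ks) expect_equal(sweep_partition(sw, k)$k, k)
  sw2 <- dynamical_communities_sweep(pert, seed = 6)
  expect_identical(lapply(sw$partitions, `[[`, "assignment"),
                   lapply(sw2$partitions, `[[`, "assignment"))
})

test_that("a 3-node network sweeps only k = 2", {
  a <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  sw <- dynamical_communities_sweep(a, seed = 1)
  expect_equal(sw$ks, 2L)
  expect_length(sw$partitions, 1L)
})

test_that("the sweep finds the planted partition of an exact network", {
  g <- planted_study_network(seed = 1)
  sw <- dynamical_communities_sweep(g$network, k_max = 6, seed = 9)
  expect_partition_equal(sweep_partition(sw, 5), g$partition)
  expect_lt(correction_cost(g$network, sweep_partition(sw, 5)), 1e-9)
})

test_that("tiny noise leaves the sweep nested around the true k", {
  g <- planted_study_network(seed = 2, sizes = small_sizes)
  pert <- perturb(g$network, 1e-5, "type1", seed = 4)
  sw <- dynamical_communities_sweep(pert, k_max = 10, seed = 5)
  score <- sweep_nestedness(sw)
  nested <- attr(score, "nested")
  expect_gte(score, 0); expect_lte(score, 1)
  # entering and leaving the planted resolution breaks one cluster at
  # a time: the 4 -> 5 and 5 -> 6 transitions refine
  expect_true(nested[["4"]])
  expect_true(nested[["5"]])
})
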