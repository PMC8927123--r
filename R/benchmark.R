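# Benchmarking against community structure: trajectory-derived
# reference partitions, pair-counting Jaccard, and a greedy-modularity
# hierarchy.

#' Reference partition from node trajectories
#'
#' Clusters the nodes by k-means on their trajectory samples (each node
#' featurized as its sampled state time series), giving a partition of
#' "who actually moves together" against which structural methods can
#' be scored.  Seeding is k-means++ on the feature rows with
#' `n_restarts` independent restarts; the run with the lowest total
#' within-cluster sum of squares wins.  When the trajectories contain
#' fewer than `k` distinct rows (exactly synchronized groups), the
#' distinct groups are returned and the largest groups are split by
#' node order until `k` clusters exist — any such partition attains the
#' optimal objective 0.
#'
#' @param traj A `trajectory_set` (typically [consensus_trajectories()]
#'   sampled on `[0, settling_time]`).
#' @param k Number of clusters, `2 <= k <= N - 1`.
#' @param n_restarts Number of k-means restarts.
#' @param seed Integer seed; deterministic given it.
#' @return A [node_partition()].
#' @export
trajectory_benchmark_partition <- function(traj, k, n_restarts = 20,
                                           seed = NULL) {
  x <- traj_component(traj)
  n <- nrow(x)
  if (k < 2 || k > n - 1) stop("k must be in 2..N-1, got ", k)
  keys <- apply(x, 1L, paste, collapse = "\r")
  if (length(unique(keys)) < k) {
    return(split_to_k(node_partition(match(keys, unique(keys))), k))
  }
  with_seed(seed, {
    subseeds <- draw_subseeds(n_restarts)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(subseeds[r])
      centers <- x[kmeanspp_rows(x, k), , drop = FALSE]
      km <- tryCatch(
        suppressWarnings(stats::kmeans(x, centers = centers,
                                       iter.max = 200,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (is.null(km)) next
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    if (is.null(best)) stop("k-means failed for every restart at k = ", k)
    node_partition(best$cluster)
  })
}

# k-means++ seeding over the rows of x; returns k row indices.
# Rows identical to an already chosen center have probability zero, so
# the chosen centers are always distinct when k distinct rows exist.
kmeanspp_rows <- function(x, k) {
  n <- nrow(x)
  centers <- sample.int(n, 1L)
  d2 <- rowSums((x - matrix(x[centers, ], n, ncol(x), byrow = TRUE))^2)
  while (length(centers) < k) {
    pr <- d2
    pr[centers] <- 0
    nxt <- if (sum(pr) > 0) sample.int(n, 1L, prob = pr) else {
      cand <- setdiff(seq_len(n), centers)
      cand[sample.int(length(cand), 1L)]
    }
    centers <- c(centers, nxt)
    d2 <- pmin(d2, rowSums((x - matrix(x[nxt, ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  centers
}

# Split the largest clusters (peeling their highest-index member into a
# new singleton) until the partition has exactly k clusters.
split_to_k <- function(part, k) {
  assign <- part$assignment
  while (max(assign) < k) {
    sizes <- tabulate(assign)
    big <- which.max(sizes)
    victim <- max(which(assign == big))
    assign[victim] <- max(assign) + 1L
  }
  node_partition(assign)
}

#' Pair-counting Jaccard similarity of two partitions
#'
#' Over all unordered node pairs, counts `n11` (together in both
#' partitions), `n10` (together only in the first), `n01` (together
#' only in the second) and `n00`, and returns
#' `J = n11 / (n11 + n10 + n01)` (0 when the denominator vanishes).
#' `J = 1` iff the partitions coincide up to cluster relabeling.
#'
#' @param p1,p2 Partitions of the same node set.
#' @return Object of class `partition_similarity`: list with `jaccard`,
#'   `n11`, `n10`, `n01`, `n00`.
#' @examples
#' jaccard_index(c(1, 1, 2, 2), c(1, 1, 1, 2))$jaccard  # 0.25
#' @export
jaccard_index <- function(p1, p2) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2)
  if (length(p1$assignment) != length(p2$assignment)) {
    stop("partitions cover different numbers of nodes")
  }
  n <- length(p1$assignment)
  tab <- table(p1$assignment, p2$assignment)
  pairs2 <- function(x) sum(choose(x, 2))
  n11 <- pairs2(tab)
  n1x <- pairs2(rowSums(tab))
  nx1 <- pairs2(colSums(tab))
  n10 <- n1x - n11
  n01 <- nx1 - n11
  n00 <- choose(n, 2) - n11 - n10 - n01
  denom <- n11 + n10 + n01
  structure(
    list(jaccard = if (denom > 0) n11 / denom else 0,
         n11 = n11, n10 = n10, n01 = n01, n00 = n00),
    class = "partition_similarity"
  )
}

#' @export
print.partition_similarity <- function(x, ...) {
  cat("Pair-counting Jaccard:", format(x$jaccard), "\n")
  cat("  n11 =", x$n11, " n10 =", x$n10, " n01 =", x$n01,
      " n00 =", x$n00, "\n")
  invisible(x)
}

#' Hierarchical community structure at every cluster count
#'
#' Greedy modularity agglomeration (fast-greedy, via
#' [igraph::cluster_fast_greedy()]) on the symmetrized network
#' `(A + A')/2`, recording the full merge dendrogram; cutting the
#' dendrogram yields a partition for every `k = 2..N-1`.  Asymmetric
#' input is symmetrized with a warning; negative weights (possible
#' after additive noise) are clamped to zero with a warning, since
#' modularity requires nonnegative weights.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @return List of [node_partition()]s named by `k`; entries are `NULL`
#'   for `k` below the number of connected components (no dendrogram
#'   cut exists there).
#' @export
community_structure_hierarchy <- function(net) {
  a <- as_adjacency(net)
  n <- nrow(a)
  if (!isSymmetric(unname(a), tol = 1e-12)) {
    warning("asymmetric network symmetrized as (A + t(A))/2 for ",
            "community structure")
  }
  s <- (a + t(a)) / 2
  if (any(s < 0)) {
    warning("negative weights clamped to zero for modularity")
    s[s < 0] <- 0
  }
  diag(s) <- 0
  g <- igraph::graph_from_adjacency_matrix(s, mode = "undirected",
                                           weighted = TRUE)
  fc <- igraph::cluster_fast_greedy(g)
  out <- vector("list", n - 2L)
  names(out) <- as.character(2:(n - 1L))
  for (k in 2:(n - 1L)) {
    memb <- tryCatch(igraph::cut_at(fc, no = k), error = function(e) NULL)
    if (!is.null(memb)) out[[as.character(k)]] <- node_partition(memb)
  }
  out
}

#' Jaccard curves: dynamical communities vs community structure
#'
#' Runs the full comparison: consensus trajectories on
#' `[0, settling_time]` (100 samples) define the benchmark partitions
#' via [trajectory_benchmark_partition()]; the dynamical-community
#' sweep and the community-structure hierarchy are each scored against
#' the benchmark with the pair-counting Jaccard index, per `k`.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param k_max Largest `k` compared; defaults to `N - 1`.
#' @param rho Consensus damping; defaults to [choose_rho()].
#' @param n_restarts Restarts for both clusterers.
#' @param seed Integer seed.
#' @return data.frame with columns `k`, `j_dyncomm`, `j_community`
#'   (`NA` where no community-structure cut exists).
#' @export
compare_methods <- function(net, k_max = NULL, rho = NULL,
                            n_restarts = 20, seed = NULL) {
  a <- as_adjacency(net)
  n <- nrow(a)
  k_max <- as.integer(k_max %||% (n - 1L))
  rho <- rho %||% choose_rho(a)
  times <- seq(0, settling_time(a, rho), length.out = 100)
  traj <- consensus_trajectories(a, rho = rho, times = times)
  with_seed(seed, {
    sweep_seed <- draw_subseeds(1L)
    bench_seeds <- draw_subseeds(k_max)
    sweep <- dynamical_communities_sweep(a, k_max = k_max,
                                         n_restarts = n_restarts,
                                         seed = sweep_seed)
    comm <- community_structure_hierarchy(a)
    ks <- 2:k_max
    j_dyn <- j_com <- rep(NA_real_, length(ks))
    for (ii in seq_along(ks)) {
      k <- ks[ii]
      bench <- trajectory_benchmark_partition(traj, k,
                                              n_restarts = n_restarts,
                                              seed = bench_seeds[k])
      j_dyn[ii] <- jaccard_index(bench, sweep_partition(sweep, k))$jaccard
      ck <- comm[[as.character(k)]]
      if (!is.null(ck)) j_com[ii] <- jaccard_index(bench, ck)$jaccard
    }
    data.frame(k = ks, j_dyncomm = j_dyn, j_community = j_com)
  })
}
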