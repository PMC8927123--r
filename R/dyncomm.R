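# Nearly equitable partitions: dissimilarity of cluster-degree rows,
# k-medoids with k-means++ seeding, and the top-down sweep over k.

#' Dissimilarity matrix of cluster-degree rows
#'
#' `D[i, j]` is the Euclidean norm of the difference between rows `i`
#' and `j` of the cluster-degree matrix: how differently the two nodes
#' are coupled to the current clusters.  `D` is symmetric, nonnegative,
#' with zero diagonal.
#'
#' @param p Cluster-degree matrix from [cluster_degree_matrix()].
#' @return Symmetric `N x N` matrix.
#' @export
dissimilarity_matrix <- function(p) {
  d <- as.matrix(stats::dist(p, method = "euclidean"))
  dimnames(d) <- NULL
  d
}

#' k-medoids clustering of a dissimilarity matrix
#'
#' Partitioning around medoids driven directly by a dissimilarity
#' matrix.  Each restart seeds the medoids by the k-means++ rule
#' adapted to dissimilarities (first medoid uniform, each further
#' medoid drawn with probability proportional to the squared
#' dissimilarity to the nearest medoid already chosen), then alternates
#' assignment to the nearest medoid (ties to the lowest medoid index)
#' with the exhaustive within-cluster medoid update until the
#' assignment stabilizes.  If an assignment step empties a cluster, the
#' point currently farthest from its own medoid is reseeded as that
#' cluster's medoid, so exactly `k` non-empty clusters are always
#' returned.  Across restarts, the partition with the lowest mean
#' point-to-own-medoid dissimilarity wins.
#'
#' @param d Symmetric nonnegative dissimilarity matrix.
#' @param k Number of clusters, `2 <= k <= N - 1`.
#' @param n_restarts Number of independent restarts.
#' @param seed Integer seed; the result is deterministic given it.
#' @param max_iter Iteration cap per restart.
#' @return A [node_partition()] with attributes `objective` (mean
#'   dissimilarity to own medoid) and `medoids` (node indices).
#' @export
kmedoids <- function(d, k, n_restarts = 20, seed = NULL, max_iter = 300) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 2 || k > n - 1) stop("k must be in 2..N-1, got ", k)
  with_seed(seed, {
    subseeds <- draw_subseeds(n_restarts)
    best <- NULL
    for (r in seq_len(n_restarts)) {
      set.seed(subseeds[r])
      res <- kmedoids_once(d, k, max_iter)
      if (is.null(best) || res$objective < best$objective) best <- res
    }
    part <- node_partition(best$assignment)
    attr(part, "objective") <- best$objective
    attr(part, "medoids") <- best$medoids
    part
  })
}

# One seeded k-medoids run; uses the current RNG stream.
kmedoids_once <- function(d, k, max_iter) {
  n <- nrow(d)
  # k-means++ seeding on squared dissimilarities
  medoids <- sample.int(n, 1L)
  d2 <- d[, medoids]^2
  while (length(medoids) < k) {
    pr <- d2
    pr[medoids] <- 0
    nxt <- if (sum(pr) > 0) {
      sample.int(n, 1L, prob = pr)
    } else {
      cand <- setdiff(seq_len(n), medoids)
      cand[sample.int(length(cand), 1L)]
    }
    medoids <- c(medoids, nxt)
    d2 <- pmin(d2, d[, nxt]^2)
  }
  assign <- integer(n)
  for (it in seq_len(max_iter)) {
    dm <- d[, medoids, drop = FALSE]
    new_assign <- max.col(-dm, ties.method = "first")
    new_assign[medoids] <- seq_len(k)  # a medoid anchors its own cluster
    # reseed empty clusters with the globally worst-served point
    repeat {
      counts <- tabulate(new_assign, k)
      empty <- which(counts == 0L)
      if (length(empty) == 0L) break
      own <- dm[cbind(seq_len(n), new_assign)]
      own[medoids] <- -Inf
      far <- which.max(own)
      medoids[empty[1L]] <- far
      dm <- d[, medoids, drop = FALSE]
      new_assign <- max.col(-dm, ties.method = "first")
      new_assign[medoids] <- seq_len(k)
    }
    if (identical(new_assign, assign)) break
    assign <- new_assign
    # exhaustive medoid update: within-cluster dissimilarity-sum minimizer
    for (c in seq_len(k)) {
      members <- which(assign == c)
      sums <- colSums(d[members, members, drop = FALSE])
      medoids[c] <- members[which.min(sums)]
    }
  }
  objective <- mean(d[cbind(seq_len(n), medoids[assign])])
  list(assignment = assign, medoids = medoids, objective = objective)
}

#' Sweep of dynamical-community partitions over the number of clusters
#'
#' Top-down detection of nearly equitable partitions.  Starting from
#' the single-cluster partition, for each `k = 2..k_max` the
#' cluster-degree matrix is computed against the current partition, its
#' dissimilarity matrix is clustered by [kmedoids()] into `k` groups,
#' and the result both is recorded and becomes the current partition
#' for the next `k`.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param k_max Largest number of clusters; defaults to `N - 1` (the
#'   all-singletons partition is excluded as trivial).
#' @param n_restarts Restarts per [kmedoids()] call.
#' @param seed Integer seed; the sweep is deterministic given it.
#' @param inner_iters Number of times the degree/cluster step is
#'   repeated at each fixed `k` (the partition usually stabilizes after
#'   one pass; values above 1 re-derive the cluster degrees from the
#'   latest partition until it stops changing).
#' @return Object of class `dyncomm_sweep`: list with `ks` and
#'   `partitions` (list indexed by as.character(k)).
#' @export
dynamical_communities_sweep <- function(net, k_max = NULL, n_restarts = 20,
                                        seed = NULL, inner_iters = 1) {
  a <- as_adjacency(net)
  n <- nrow(a)
  if (n < 3) stop("need at least 3 nodes to sweep k = 2..N-1")
  k_max <- as.integer(k_max %||% (n - 1L))
  if (k_max < 2L || k_max > n - 1L) stop("k_max must be in 2..N-1")
  with_seed(seed, {
    part <- node_partition(rep(1L, n))
    partitions <- vector("list", k_max - 1L)
    for (k in 2:k_max) {
      for (pass in seq_len(max(1L, inner_iters))) {
        p <- cluster_degree_matrix(a, part)
        d <- dissimilarity_matrix(p)
        new_part <- kmedoids(d, k, n_restarts = n_restarts,
                             seed = draw_subseeds(1L))
        stable <- same_partition(new_part, part)
        part <- new_part
        if (stable) break
      }
      partitions[[k - 1L]] <- part
    }
    names(partitions) <- as.character(2:k_max)
    structure(list(ks = 2:k_max, partitions = partitions),
              class = "dyncomm_sweep")
  })
}

#' @export
print.dyncomm_sweep <- function(x, ...) {
  cat("Dynamical-community sweep over k =", min(x$ks), "..", max(x$ks), "\n")
  invisible(x)
}

#' Nestedness diagnostic of a sweep
#'
#' Fraction of consecutive sweep transitions `k -> k + 1` in which the
#' partition at `k + 1` refines the partition at `k` (every new cluster
#' sits inside one old cluster).  On networks with clear nearly
#' equitable structure the sweep often — not always — breaks one
#' cluster at a time, and this score quantifies that tendency.
#'
#' @param sweep A `dyncomm_sweep`.
#' @return Fraction in `[0, 1]`, with attribute `nested` (logical per
#'   transition, named by the coarser `k`).
#' @export
sweep_nestedness <- function(sweep) {
  ks <- sweep$ks
  if (length(ks) < 2L) return(structure(NA_real_, nested = logical(0)))
  nested <- vapply(ks[-length(ks)], function(k) {
    coarse <- sweep_partition(sweep, k)$assignment
    fine <- sweep_partition(sweep, k + 1L)$assignment
    all(vapply(split(coarse, fine),
               function(x) length(unique(x)) == 1L, logical(1)))
  }, logical(1))
  names(nested) <- ks[-length(ks)]
  structure(mean(nested), nested = nested)
}

#' Extract the partition at a given number of clusters
#'
#' @param sweep A `dyncomm_sweep`.
#' @param k Number of clusters.
#' @return A [node_partition()].
#' @export
sweep_partition <- function(sweep, k) {
  p <- sweep$partitions[[as.character(k)]]
  if (is.null(p)) stop("sweep has no partition at k = ", k)
  p
}
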