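# Exact equitable partitions by iterative refinement of cluster degrees
# (the balanced-coloring construction of Belykh and Hasler).

#' Cluster-degree matrix
#'
#' The `N x k` matrix `P` whose entry `P[i, j]` is the total weight node
#' `i` receives from the nodes of cluster `j`.  Row sums of `P` equal
#' the row sums of the adjacency matrix (weight conservation).
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param part A [node_partition()] of the network's nodes.
#' @return `N x k` numeric matrix.
#' @export
cluster_degree_matrix <- function(net, part) {
  a <- as_adjacency(net)
  part <- as_partition(part)
  if (length(part$assignment) != nrow(a)) {
    stop("partition covers ", length(part$assignment),
         " nodes but the network has ", nrow(a))
  }
  p <- a %*% indicator_matrix(part)
  dimnames(p) <- NULL
  p
}

#' One refinement step of a partition by cluster degrees
#'
#' Nodes stay together iff they already shared a cluster *and* their
#' rows of the cluster-degree matrix agree entrywise within `tol`.
#' Refinement can only split clusters, never merge them.  At `tol > 0`
#' approximate row equality is not transitive; groups are formed
#' greedily in node-index order (a node joins the first group whose
#' representative row matches), which makes the result reproducible.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param part A [node_partition()].
#' @param tol Nonnegative entrywise tolerance for row equality.
#' @return The refined [node_partition()], in canonical form.
#' @export
refine_partition <- function(net, part, tol = 1e-9) {
  if (tol < 0) stop("tol must be >= 0")
  part <- as_partition(part)
  p <- cluster_degree_matrix(net, part)
  new_assign <- integer(length(part$assignment))
  next_id <- 0L
  for (members in cluster_members(part)) {
    if (tol == 0) {
      keys <- apply(p[members, , drop = FALSE], 1L, paste, collapse = "\r")
      grp <- match(keys, unique(keys))
    } else {
      grp <- integer(length(members))
      reps <- integer(0)  # representative node of each group, in order
      for (ii in seq_along(members)) {
        row <- p[members[ii], ]
        hit <- 0L
        for (g in seq_along(reps)) {
          if (all(abs(row - p[reps[g], ]) <= tol)) { hit <- g; break }
        }
        if (hit == 0L) {
          reps <- c(reps, members[ii])
          hit <- length(reps)
        }
        grp[ii] <- hit
      }
    }
    new_assign[members] <- next_id + grp
    next_id <- next_id + max(grp)
  }
  node_partition(new_assign)
}

#' Minimum balanced coloring by iterated refinement
#'
#' Starting from all nodes in one cluster, [refine_partition()] is
#' iterated until a fixed point is reached.  The fixed point is an
#' equitable partition (at tolerance `tol`) using the minimum number of
#' clusters; the iteration terminates in at most `N` steps because the
#' cluster count strictly increases until the fixed point.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param tol Nonnegative entrywise tolerance for row equality.
#' @return A [node_partition()]; its `k` is the true cluster count.
#' @examples
#' g <- planted_equitable_network(c(3, 2), seed = 1)
#' minimum_balanced_coloring(g$network)$k  # 2
#' @export
minimum_balanced_coloring <- function(net, tol = 1e-9) {
  a <- as_adjacency(net)
  part <- node_partition(rep(1L, nrow(a)))
  for (it in seq_len(nrow(a))) {
    refined <- refine_partition(a, part, tol)
    if (refined$k == part$k) return(refined)
    part <- refined
  }
  part
}

#' Is a partition equitable for a network?
#'
#' TRUE iff, within every cluster, all rows of the cluster-degree
#' matrix agree entrywise within `tol` — i.e. every node of a cluster
#' receives the same total weight from each cluster.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param part A [node_partition()].
#' @param tol Nonnegative entrywise tolerance.
#' @return Logical scalar.
#' @export
is_equitable <- function(net, part, tol = 1e-9) {
  equitability_error(net, part) <= tol
}

#' Largest within-cluster disagreement of cluster degrees
#'
#' The maximum, over clusters and columns, of the spread (max minus
#' min) of cluster-degree entries among the cluster's members.  Zero
#' for an exactly equitable partition.
#'
#' @inheritParams is_equitable
#' @return Nonnegative scalar.
#' @export
equitability_error <- function(net, part) {
  part <- as_partition(part)
  p <- cluster_degree_matrix(net, part)
  worst <- 0
  for (members in cluster_members(part)) {
    rows <- p[members, , drop = FALSE]
    spread <- apply(rows, 2L, max) - apply(rows, 2L, min)
    worst <- max(worst, spread)
  }
  worst
}
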