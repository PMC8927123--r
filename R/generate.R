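# Synthetic networks with planted equitable partitions, and the two
# noise models used to degrade them.

#' Specification of a planted equitable partition
#'
#' Describes the quotient structure of a network to generate:
#' `cluster_sizes[u]` nodes in cluster `u`, and every node of cluster
#' `u` receiving a total weight of exactly `quotient_weights[u, v]` from
#' the nodes of cluster `v`.
#'
#' @param cluster_sizes Positive integers; their sum is the network size.
#' @param quotient_weights `k x k` nonnegative matrix of per-node target
#'   cluster in-weights.  `NULL` builds a default quotient when the
#'   network is generated: a cyclic Latin square over the well-spaced
#'   value set `1, 3, ..., 2k - 1` with randomly permuted rows, plus a
#'   small per-receiver-cluster offset of `strength_step * (u - 1)`.
#'   The Latin structure makes every pair of clusters differ in every
#'   cluster-degree coordinate (strong full-resolution contrast) while
#'   keeping the per-node total in-weight nearly uniform across
#'   clusters, so coarse aggregates of the network look generic; the
#'   small offset breaks the remaining strength ties so the sweep is
#'   well determined on the unperturbed network.
#' @param block_density Fraction in `(0, 1]` of admissible entries kept
#'   per block row.
#' @param strength_step Spacing of the per-cluster strength offsets used
#'   by the default quotient; ignored when `quotient_weights` is given.
#' @return An object of class `quotient_spec`.
#' @export
quotient_spec <- function(cluster_sizes, quotient_weights = NULL,
                          block_density = 0.5, strength_step = 0.5) {
  cluster_sizes <- as.integer(cluster_sizes)
  if (any(cluster_sizes < 1L)) stop("cluster sizes must be positive")
  k <- length(cluster_sizes)
  if (!is.null(quotient_weights)) {
    quotient_weights <- as.matrix(quotient_weights)
    if (!all(dim(quotient_weights) == k)) {
      stop("quotient_weights must be ", k, " x ", k)
    }
    if (any(quotient_weights < 0)) stop("quotient weights must be >= 0")
  }
  if (block_density <= 0 || block_density > 1) {
    stop("block_density must be in (0, 1]")
  }
  structure(
    list(cluster_sizes = cluster_sizes, quotient_weights = quotient_weights,
         block_density = block_density, strength_step = strength_step),
    class = "quotient_spec"
  )
}

#' Generate a network with an exactly equitable planted partition
#'
#' Construction: for every block (receiver cluster `u`, source cluster
#' `v`) with nonzero target weight, a random sparsity pattern over the
#' admissible entries (self-loops excluded) is filled with positive
#' uniform weights and then Sinkhorn-balanced so that every block row
#' sums to `quotient_weights[u, v]` and every block column to
#' `size[u] * quotient_weights[u, v] / size[v]`.  The planted partition
#' is therefore equitable for both received and sent cluster weights,
#' which is the condition under which the adjacency matrix commutes
#' with the partition's projector and the correction cost vanishes
#' exactly.  If the sampled pattern cannot support the required
#' margins, the block falls back to the full admissible pattern.
#'
#' @param spec A [quotient_spec()], or a vector of cluster sizes.
#' @param seed Integer seed; the construction is deterministic given it.
#' @return List with elements `network` (a [weighted_network()]),
#'   `partition` (the planted [node_partition()]) and `quotient` (the
#'   `k x k` quotient matrix actually used).
#' @examples
#' g <- planted_equitable_network(c(3, 2), seed = 1)
#' is_equitable(g$network, g$partition)
#' @export
planted_equitable_network <- function(spec, seed = NULL) {
  if (!inherits(spec, "quotient_spec")) spec <- quotient_spec(spec)
  sizes <- spec$cluster_sizes
  k <- length(sizes)
  n <- sum(sizes)
  assignment <- rep(seq_len(k), sizes)
  members <- split(seq_len(n), assignment)
  with_seed(seed, {
    q <- spec$quotient_weights %||% default_quotient(k, spec$strength_step)
    a <- matrix(0, n, n)
    for (u in seq_len(k)) {
      for (v in seq_len(k)) {
        if (q[u, v] == 0) next
        rows <- members[[u]]
        cols <- members[[v]]
        if (u == v && length(cols) == 1L) {
          stop("infeasible spec: cluster ", u, " is a singleton but its ",
               "diagonal quotient weight is nonzero (self-loop required)")
        }
        a[rows, cols] <- balanced_block(
          m = length(rows), p = length(cols),
          row_target = q[u, v],
          density = spec$block_density,
          forbid_diag = (u == v)
        )
      }
    }
    list(network = weighted_network(a),
         partition = node_partition(assignment),
         quotient = q)
  })
}

# Default quotient: cyclic Latin square over 1, 3, ..., 2k-1 with
# randomly permuted rows, plus per-receiver-cluster strength offsets.
# Uses the current RNG stream (called inside the generator's seed scope).
default_quotient <- function(k, strength_step) {
  vals <- 1 + 2 * (0:(k - 1))
  lat <- outer(0:(k - 1), 0:(k - 1), function(i, j) (i + j) %% k) + 1L
  if (k > 1) lat <- lat[sample.int(k), , drop = FALSE]
  q <- matrix(vals[lat], k, k) + strength_step * (seq_len(k) - 1L)
  # global scale chosen so per-node total in-weights are ~10 at k = 5,
  # keeping gamma * strength ~ 0.1 (weak coupling) for the standard
  # oscillator setup; every detection statistic is invariant under this
  # uniform rescaling of A
  q / 3
}

# One block of the planted construction: an m x p nonnegative matrix
# with every row summing to row_target and every column to
# m * row_target / p, on a random sparsity pattern (diagonal excluded
# for within-cluster blocks).  Margins are imposed by Sinkhorn scaling;
# a final row scaling makes the row sums exact to roundoff.
balanced_block <- function(m, p, row_target, density, forbid_diag,
                           tol = 1e-13, maxit = 5000L) {
  col_target <- m * row_target / p
  make_pattern <- function(full) {
    pat <- matrix(if (full) TRUE else stats::runif(m * p) < density, m, p)
    if (forbid_diag) diag(pat) <- FALSE
    # every row and column needs at least one admissible entry
    for (i in which(rowSums(pat) == 0L)) {
      adm <- if (forbid_diag) setdiff(seq_len(p), i) else seq_len(p)
      pat[i, adm[sample.int(length(adm), 1L)]] <- TRUE
    }
    for (j in which(colSums(pat) == 0L)) {
      adm <- if (forbid_diag) setdiff(seq_len(m), j) else seq_len(m)
      pat[adm[sample.int(length(adm), 1L)], j] <- TRUE
    }
    pat
  }
  balance <- function(pat) {
    w <- matrix(0, m, p)
    w[pat] <- stats::runif(sum(pat), 0.5, 1.5)
    for (it in seq_len(maxit)) {
      w <- w * (row_target / rowSums(w))
      cs <- colSums(w)
      if (max(abs(cs - col_target)) <= tol * col_target) break
      w <- sweep(w, 2L, col_target / cs, "*")
    }
    w <- w * (row_target / rowSums(w))
    if (max(abs(colSums(w) - col_target)) > 1e-10 * col_target) NULL else w
  }
  w <- balance(make_pattern(full = FALSE))
  if (is.null(w)) w <- balance(make_pattern(full = TRUE))
  if (is.null(w)) {
    stop("block balancing failed for a ", m, " x ", p, " block")
  }
  w
}

#' Perturb a network with multiplicative or additive Gaussian noise
#'
#' Two noise models degrade a network `A0`.  With `Q` a full matrix of
#' independent standard-normal draws:
#' \describe{
#'   \item{Type I}{`A = A0 + epsilon * Q o A0` (entrywise product): only
#'     existing edges are perturbed, the zero pattern is preserved
#'     exactly.}
#'   \item{Type II}{`A = A0 + epsilon * Q`: noise lands on every ordered
#'     node pair.  The diagonal is left untouched so the network stays
#'     free of self-loops.}
#' }
#'
#' @param net A [weighted_network()].
#' @param epsilon Nonnegative noise magnitude.
#' @param kind `"type1"` (multiplicative) or `"type2"` (additive).
#' @param seed Integer seed; the perturbation is deterministic given it.
#' @return A perturbed [weighted_network()] with the same labels.
#' @export
perturb <- function(net, epsilon, kind = c("type1", "type2"), seed = NULL) {
  kind <- match.arg(kind)
  if (epsilon < 0) stop("epsilon must be >= 0")
  a <- as_adjacency(net)
  n <- nrow(a)
  with_seed(seed, {
    q <- matrix(stats::rnorm(n * n), n, n)
    out <- switch(kind,
      type1 = a + epsilon * q * a,
      type2 = {
        diag(q) <- 0
        a + epsilon * q
      }
    )
    weighted_network(out,
                     labels = if (inherits(net, "weighted_network"))
                       net$labels else NULL,
                     allow_self_loops = any(diag(out) != 0))
  })
}
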