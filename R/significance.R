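# Statistical significance of the correction-cost profile against a
# weight-shuffled null ensemble.

# The elementary shuffling move: given pairwise-distinct indices
# i, j, l, m, exchange
#   A[i,j] <-> A[i,l],  A[j,i] <-> A[l,i],  A[m,j] <-> A[m,l],
#   A[j,m] <-> A[l,m].
# All eight touched entries are off-diagonal, so the move permutes the
# off-diagonal entry multiset and leaves the diagonal alone.
apply_quad_swap <- function(a, i, j, l, m) {
  swp <- function(a, r1, c1, r2, c2) {
    tmp <- a[r1, c1]; a[r1, c1] <- a[r2, c2]; a[r2, c2] <- tmp
    a
  }
  a <- swp(a, i, j, i, l)
  a <- swp(a, j, i, l, i)
  a <- swp(a, m, j, m, l)
  a <- swp(a, j, m, l, m)
  a
}

#' Shuffle a network's weights by random entry swaps
#'
#' Performs `n_s` rounds of the elementary move: draw four
#' pairwise-distinct node indices `i, j, l, m` uniformly and exchange
#' the weight pairs `A[i,j] <-> A[i,l]`, `A[j,i] <-> A[l,i]`,
#' `A[m,j] <-> A[m,l]`, `A[j,m] <-> A[l,m]`.  Each move is a
#' permutation of off-diagonal entries, so the multiset of off-diagonal
#' weights (and hence the total weight) is preserved exactly, while the
#' arrangement — and with it any nearly equitable structure — is
#' destroyed.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param n_s Number of shuffling rounds; default `10 x` the number of
#'   nonzero off-diagonal entries.
#' @param seed Integer seed; deterministic given it.
#' @return A shuffled [weighted_network()] with the same labels.
#' @export
shuffle_network <- function(net, n_s = NULL, seed = NULL) {
  a <- as_adjacency(net)
  n <- nrow(a)
  if (n < 4) stop("shuffling needs at least 4 nodes")
  n_s <- as.integer(n_s %||% (10L * n_edges(a)))
  if (n_s < 0) stop("n_s must be >= 0")
  with_seed(seed, {
    for (s in seq_len(n_s)) {
      idx <- sample.int(n, 4L)  # pairwise distinct by construction
      a <- apply_quad_swap(a, idx[1L], idx[2L], idx[3L], idx[4L])
    }
    weighted_network(a,
                     labels = if (inherits(net, "weighted_network"))
                       net$labels else NULL,
                     allow_self_loops = any(diag(a) != 0))
  })
}

#' Significance profile of the correction cost
#'
#' Compares the correction-cost profile of the actual network with
#' that of an ensemble of `n_random` shuffled networks.  Each replicate
#' is independently shuffled, swept with
#' [dynamical_communities_sweep()] under the same restart budget as the
#' actual run, and costed with [cost_profile()]; the per-`k` mean and
#' standard deviation of the randomized `psi` define the significance
#' band.  `k_min` is the smallest `k` whose actual cost falls more than
#' `3` standard deviations below the randomized mean; when no `k`
#' qualifies, no statistically significant nearly equitable partition
#' exists and `k_min` is `NA`.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param k_max Largest `k` swept; defaults to `N - 1`.
#' @param n_random Ensemble size (100 by default).
#' @param n_s Shuffling rounds per replicate; see [shuffle_network()].
#' @param n_restarts Restarts per [kmedoids()] call.
#' @param n_sigma Width of the significance rule (3 by default).
#' @param seed Integer seed; deterministic given it.
#' @return Object of class `significance_result`: list with `ks`,
#'   `psi_actual`, `mean_rand`, `std_rand`, `significant` (logical per
#'   k), `k_min` (integer or `NA`), `n_random`, `n_s`, and the actual
#'   `sweep`.
#' @export
significance_profile <- function(net, k_max = NULL, n_random = 100,
                                 n_s = NULL, n_restarts = 20, n_sigma = 3,
                                 seed = NULL) {
  a <- as_adjacency(net)
  n <- nrow(a)
  k_max <- as.integer(k_max %||% (n - 1L))
  n_s <- as.integer(n_s %||% (10L * n_edges(a)))
  with_seed(seed, {
    actual_seed <- draw_subseeds(1L)
    rep_seeds <- draw_subseeds(2L * n_random)
    sweep <- dynamical_communities_sweep(a, k_max = k_max,
                                         n_restarts = n_restarts,
                                         seed = actual_seed)
    actual <- cost_profile(a, sweep)
    rand_psi <- matrix(NA_real_, n_random, k_max - 1L)
    for (r in seq_len(n_random)) {
      shuf <- shuffle_network(a, n_s = n_s, seed = rep_seeds[2L * r - 1L])
      rsweep <- dynamical_communities_sweep(shuf, k_max = k_max,
                                            n_restarts = n_restarts,
                                            seed = rep_seeds[2L * r])
      rand_psi[r, ] <- cost_profile(shuf, rsweep)$psi
    }
    mean_rand <- colMeans(rand_psi)
    std_rand <- apply(rand_psi, 2L, stats::sd)
    significant <- actual$psi < mean_rand - n_sigma * std_rand
    k_min <- if (any(significant)) actual$k[which(significant)[1L]]
             else NA_integer_
    structure(
      list(ks = actual$k, psi_actual = actual$psi, mean_rand = mean_rand,
           std_rand = std_rand, significant = significant,
           k_min = as.integer(k_min), n_random = n_random, n_s = n_s,
           sweep = sweep),
      class = "significance_result"
    )
  })
}

#' @export
print.significance_result <- function(x, ...) {
  cat("Correction-cost significance over k =", min(x$ks), "..", max(x$ks),
      "(", x$n_random, "randomized networks,", x$n_s, "swaps each )\n")
  if (is.na(x$k_min)) {
    cat("  no statistically significant k: no nearly equitable",
        "partition detected\n")
  } else {
    cat("  k_min =", x$k_min,
        "(smallest k with psi below the randomized mean - 3 sd)\n")
  }
  invisible(x)
}

#' Tabulate a significance result
#'
#' @param x A `significance_result`.
#' @param ... Unused.
#' @return data.frame with columns `k`, `psi`, `mean_rand`, `std_rand`,
#'   `significant`.
#' @export
as.data.frame.significance_result <- function(x, ...) {
  data.frame(k = x$ks, psi = x$psi_actual, mean_rand = x$mean_rand,
             std_rand = x$std_rand, significant = x$significant)
}
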