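# Correction cost: the minimum-Frobenius-norm perturbation of the
# adjacency matrix that makes it commute with a partition's projector.

#' Projection operator of a partition
#'
#' The symmetric idempotent matrix `E (E'E)^-1 E'` built from the
#' partition's indicator matrix `E`; it averages vectors within
#' clusters.  Entry `(i, j)` is `1/|C|` when nodes `i` and `j` share
#' cluster `C`, and 0 otherwise.  Its trace is the number of clusters.
#'
#' @param part A [node_partition()].
#' @return Symmetric `N x N` matrix.
#' @export
cluster_projector <- function(part) {
  part <- as_partition(part)
  n <- length(part$assignment)
  eh <- matrix(0, n, n)
  for (members in cluster_members(part)) {
    eh[members, members] <- 1 / length(members)
  }
  eh
}

#' Minimum-norm commutation correction, dense pseudoinverse solver
#'
#' Solves `(A + dA) R - R (A + dA) = 0` for the minimum-Frobenius-norm
#' `dA` by building the `N^2 x N^2` Kronecker system literally and
#' applying the Moore-Penrose pseudoinverse:
#' `dA = (I (x) R - R' (x) I)^+ vec(A R - R A)`, with column-major
#' vectorization.  Exact but quartic in memory; guarded to `N <= 60`.
#' Serves as the reference implementation for [delta_A_spectral()].
#'
#' @param a Square matrix `A`.
#' @param r Symmetric matrix `R` (typically a [cluster_projector()]).
#' @return `N x N` correction matrix `dA`.
#' @export
delta_A_naive <- function(a, r) {
  a <- as_adjacency(a)
  n <- nrow(a)
  if (n > 60) {
    stop("delta_A_naive builds an N^2 x N^2 system; use delta_A_spectral ",
         "for N > 60")
  }
  if (!all(dim(r) == n)) stop("R must match A in size")
  id <- diag(n)
  m <- kronecker(id, r) - kronecker(t(r), id)
  rhs <- as.vector(a %*% r - r %*% a)
  matrix(MASS::ginv(m) %*% rhs, n, n)
}

#' Minimum-norm commutation correction, spectral solver
#'
#' Same minimum-Frobenius-norm solution as [delta_A_naive()], computed
#' in the eigenbasis of the symmetric matrix `R`:
#' with `R = U L U'` and `B = U'(R A - A R) U`, the solution has
#' eigenbasis entries `B[i, j] / (L[j] - L[i])` wherever the eigenvalue
#' gap exceeds `tol`, and 0 on the (kernel) directions where the
#' eigenvalues coincide.  Cost `O(N^3)`.
#'
#' @param a Square matrix `A`.
#' @param r Symmetric matrix `R`.
#' @param tol Eigenvalue-equality threshold for zeroing kernel
#'   directions.
#' @return `N x N` correction matrix `dA`.
#' @export
delta_A_spectral <- function(a, r, tol = 1e-10) {
  a <- as_adjacency(a)
  n <- nrow(a)
  if (!all(dim(r) == n)) stop("R must match A in size")
  if (!isSymmetric(unname(r), tol = 1e-8)) stop("R must be symmetric")
  eig <- eigen((r + t(r)) / 2, symmetric = TRUE)
  u <- eig$vectors
  lam <- eig$values
  b <- t(u) %*% (r %*% a - a %*% r) %*% u
  gap <- outer(lam, lam, function(li, lj) lj - li)  # gap[i,j] = L[j]-L[i]
  x <- ifelse(abs(gap) > tol, b / gap, 0)
  u %*% x %*% t(u)
}

#' Correction cost of a partition
#'
#' The Frobenius norm `psi = ||dA||` of the minimum-norm perturbation
#' that makes the adjacency matrix commute with the partition's
#' projector.  `psi` vanishes exactly when the partition is equitable.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param part A [node_partition()].
#' @return Nonnegative scalar.
#' @export
correction_cost <- function(net, part) {
  a <- as_adjacency(net)
  fnorm(delta_A_spectral(a, cluster_projector(part)))
}

#' Correction-cost profile of a sweep
#'
#' `psi(k)` and the scaled cost `psi_hat(k) = k * psi(k)` for every
#' partition recorded by [dynamical_communities_sweep()].  `psi`
#' decreases essentially monotonically with `k`; the scaling rewards
#' partitions with fewer, larger clusters, so a planted cluster count
#' shows up as the global minimum of `psi_hat`.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param sweep A `dyncomm_sweep` (or a list of partitions keyed by k).
#' @return Object of class `correction_profile`: data.frame with
#'   columns `k`, `psi`, `psi_hat`.
#' @export
cost_profile <- function(net, sweep) {
  a <- as_adjacency(net)
  ks <- sweep$ks
  psi <- vapply(ks, function(k) correction_cost(a, sweep_partition(sweep, k)),
                numeric(1))
  structure(data.frame(k = ks, psi = psi, psi_hat = ks * psi),
            class = c("correction_profile", "data.frame"))
}
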