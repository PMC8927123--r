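# Dynamics-based validation: linear consensus (closed form) and
# coupled Rossler oscillators.

#' Damping that makes the consensus dynamics stable
#'
#' The consensus system evolves under `A - rho I`; this returns
#' `rho = max(Re(eigenvalues(A))) + margin`, the smallest damping (plus
#' a margin) for which `A - rho I` is Hurwitz, i.e. all its eigenvalues
#' have real part `<= -margin`.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param margin Positive stability margin (default 1).
#' @return Scalar `rho`.
#' @export
choose_rho <- function(net, margin = 1.0) {
  a <- as_adjacency(net)
  max(Re(eigen(a, only.values = TRUE)$values)) + margin
}

# Verify that A - rho*I is Hurwitz; returns the spectral abscissa.
hurwitz_abscissa <- function(a, rho) {
  lam <- max(Re(eigen(a - rho * diag(nrow(a)), only.values = TRUE)$values))
  if (lam >= 0) {
    stop("A - rho I is not Hurwitz (spectral abscissa ", format(lam),
         "); increase rho, e.g. with choose_rho()")
  }
  lam
}

#' Trajectory set
#'
#' Container for node trajectories: `times` (length `T`) and `states`,
#' an `N x T` matrix for scalar node states or an `N x 3 x T` array for
#' oscillators.  `component` names the state components.
#'
#' @keywords internal
#' @noRd
trajectory_set <- function(times, states, component = NULL) {
  structure(list(times = times, states = states, component = component),
            class = "trajectory_set")
}

#' @export
print.trajectory_set <- function(x, ...) {
  dims <- dim(x$states)
  cat("Trajectory set:", dims[1L], "nodes,", length(x$times),
      "time points\n")
  invisible(x)
}

# N x T matrix of one scalar component ("x" for oscillators).
traj_component <- function(traj, component = 1L) {
  s <- traj$states
  if (length(dim(s)) == 3L) s[, component, ] else s
}

#' Closed-form consensus trajectories
#'
#' Evaluates the linear consensus dynamics
#' `dx/dt = (A - rho I) x + delta`, `x(0) = 0`, through its closed form
#' `x(t) = (A - rho I)^-1 [exp((A - rho I) t) - I] delta` at each grid
#' time (matrix exponential via [Matrix::expm()]).  On an exactly
#' equitable network, nodes of the same cluster follow identical
#' trajectories.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param rho Damping scalar; defaults to [choose_rho()].
#' @param delta Forcing vector (default all ones).
#' @param times Increasing nonnegative time grid; defaults to 100
#'   points over twice the settling time.
#' @return A `trajectory_set` with an `N x T` state matrix.
#' @export
consensus_trajectories <- function(net, rho = NULL, delta = NULL,
                                   times = NULL) {
  a <- as_adjacency(net)
  n <- nrow(a)
  rho <- rho %||% choose_rho(a)
  delta <- delta %||% rep(1, n)
  hurwitz_abscissa(a, rho)
  times <- times %||% seq(0, 2 * settling_time(a, rho), length.out = 100)
  if (is.unsorted(times, strictly = TRUE) || any(times < 0)) {
    stop("times must be strictly increasing and nonnegative")
  }
  m <- a - rho * diag(n)
  minv_delta <- solve(m, delta)
  states <- vapply(times, function(t) {
    e <- as.matrix(Matrix::expm(m * t))
    as.vector(e %*% minv_delta - minv_delta)
  }, numeric(n))
  trajectory_set(times, states)
}

#' Consensus steady state
#'
#' The fixed point `x_ss = -(A - rho I)^-1 delta` of the consensus
#' dynamics; constant within clusters for an equitable network.
#'
#' @inheritParams consensus_trajectories
#' @return Length-`N` vector.
#' @export
consensus_steady_state <- function(net, rho = NULL, delta = NULL) {
  a <- as_adjacency(net)
  rho <- rho %||% choose_rho(a)
  delta <- delta %||% rep(1, nrow(a))
  hurwitz_abscissa(a, rho)
  -solve(a - rho * diag(nrow(a)), delta)
}

#' Settling time of the consensus dynamics
#'
#' `-4 / Lambda`, with `Lambda < 0` the largest real part among the
#' eigenvalues of `A - rho I`: the time for the slowest mode to decay
#' to `exp(-4)` of its initial amplitude.
#'
#' @inheritParams consensus_trajectories
#' @return Positive scalar.
#' @export
settling_time <- function(net, rho = NULL) {
  a <- as_adjacency(net)
  rho <- rho %||% choose_rho(a)
  -4 / hurwitz_abscissa(a, rho)
}

#' Coupled Rossler oscillators on a network
#'
#' Integrates, per node `i`,
#' \deqn{dx_i = -y_i - z_i,\quad
#'       dy_i = x_i + a y_i + \gamma \sum_j A_{ij} y_j,\quad
#'       dz_i = b + z_i (x_i - c),}
#' i.e. chaotic Rossler units (defaults `a = b = 0.2`, `c = 9` give
#' chaotic uncoupled dynamics) coupled through the `y` component with
#' strength `gamma`.  Fixed-step 4th-order Runge-Kutta via
#' [deSolve::rk4()]; deterministic given `x0`.
#'
#' @param net A [weighted_network()] or adjacency matrix.
#' @param a,b,c Rossler parameters.
#' @param gamma Coupling strength.
#' @param x0 `N x 3` matrix of initial conditions (columns x, y, z); by
#'   default drawn uniformly from `[-1, 1]^3` (seeded via `seed`).
#' @param t_max Integration horizon (time units).
#' @param dt Fixed step size.
#' @param seed Seed for the default initial conditions.
#' @return A `trajectory_set` with an `N x 3 x T` state array.
#' @export
simulate_rossler <- function(net, a = 0.2, b = 0.2, c = 9.0, gamma = 0.01,
                             x0 = NULL, t_max = 500, dt = 0.01,
                             seed = NULL) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  if (dt <= 0) stop("dt must be positive")
  x0 <- x0 %||% with_seed(seed, matrix(stats::runif(3 * n, -1, 1), n, 3))
  x0 <- as.matrix(x0)
  if (!all(dim(x0) == c(n, 3))) stop("x0 must be N x 3")
  times <- seq(0, t_max, by = dt)
  rhs <- function(t, state, parms) {
    x <- state[1:n]; y <- state[(n + 1):(2 * n)]; z <- state[(2 * n + 1):(3 * n)]
    list(c(-y - z,
           x + a * y + gamma * as.vector(adj %*% y),
           b + z * (x - c)))
  }
  out <- deSolve::rk4(y = c(x0[, 1], x0[, 2], x0[, 3]), times = times,
                      func = rhs, parms = NULL)
  states_flat <- t(unname(out[, -1, drop = FALSE]))  # 3N x T
  if (!all(is.finite(states_flat)) || max(abs(states_flat)) > 1e6) {
    stop("Rossler integration diverged (state norm exceeded 1e6); ",
         "reduce dt or the coupling strength")
  }
  tt <- length(times)
  states <- array(0, dim = c(n, 3, tt))
  states[, 1, ] <- states_flat[1:n, ]
  states[, 2, ] <- states_flat[(n + 1):(2 * n), ]
  states[, 3, ] <- states_flat[(2 * n + 1):(3 * n), ]
  trajectory_set(times, states, component = c("x", "y", "z"))
}

#' Maximum intra-cluster spread of trajectories
#'
#' For each cluster, the maximum over time of the standard deviation of
#' the member states (first state component for oscillators).  Zero for
#' exact cluster-synchronized motion; grows with the perturbation
#' magnitude of a nearly equitable network.
#'
#' @param traj A `trajectory_set`.
#' @param part A [node_partition()].
#' @return Length-`k` vector of nonnegative spreads.
#' @export
cluster_spread <- function(traj, part) {
  part <- as_partition(part)
  m <- traj_component(traj)
  vapply(cluster_members(part), function(members) {
    if (length(members) < 2L) return(0)
    sub <- m[members, , drop = FALSE]
    max(apply(sub, 2L, stats::sd))
  }, numeric(1))
}

#' Group nodes whose trajectories stay together
#'
#' Builds the relation "nodes `i` and `j` have
#' `max_t |x_i(t) - x_j(t)| < tol`" over the retained times and counts
#' the connected components of its graph: the number of distinct
#' synchronized trajectory groups.
#'
#' @param traj A `trajectory_set`.
#' @param tol Pairwise trajectory-difference tolerance.
#' @param discard Initial transient (time units) to drop.
#' @return A [node_partition()] of the nodes into synchronized groups;
#'   its `k` is the group count.
#' @export
synchronized_groups <- function(traj, tol = 1e-6, discard = 0) {
  m <- traj_component(traj)
  keep <- traj$times >= discard
  m <- m[, keep, drop = FALSE]
  n <- nrow(m)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1L)) {
    diffs <- abs(m[(i + 1L):n, , drop = FALSE] -
                   matrix(m[i, ], n - i, ncol(m), byrow = TRUE))
    close <- apply(diffs, 1L, max) < tol
    adj[i, (i + 1L):n] <- close
    adj[(i + 1L):n, i] <- close
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  node_partition(igraph::components(g)$membership)
}
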