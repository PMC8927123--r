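test_that("choose_rho lands the spectral abscissa at -margin", {
  expect_equal(choose_rho(matrix(0, 3, 3)), 1.0)
  sym <- matrix(c(0, 2, 2, 0), 2, 2)
  expect_equal(choose_rho(sym), 3.0)  # spectral radius 2 + margin 1
  set.seed(6)
  a <- matrix(stats::rexp(100) * (stats::runif(100) < 0.4), 10, 10)
  diag(a) <- 0
  rho <- choose_rho(a)
  abscissa <- max(Re(eigen(a - rho * diag(10), only.values = TRUE)$values))
  expect_equal(abscissa, -1.0, tolerance = 1e-9)
})

test_that("consensus on the empty network matches 1 - exp(-t)", {
  times <- seq(0, 5, length.out = 21)
  traj <- consensus_trajectories(matrix(0, 3, 3), rho = 1, times = times)
  expect_equal(dim(traj$states), c(3, 21))
  for (i in 1:3) {
    expect_equal(traj$states[i, ], 1 - exp(-times), tolerance = 1e-10)
  }
  expect_equal(consensus_steady_state(matrix(0, 3, 3), rho = 1), rep(1, 3))
})

test_that("closed-form consensus matches an adaptive ODE integration", {
  set.seed(3)
  a <- matrix(stats::rexp(64) * (stats::runif(64) < 0.5), 8, 8)
  diag(a) <- 0
  rho <- choose_rho(a)
  times <- seq(0, 6, length.out = 31)
  traj <- consensus_trajectories(a, rho = rho, times = times)
  m <- a - rho * diag(8)
  ode <- deSolve::ode(y = rep(0, 8), times = times,
                      func = function(t, x, p) list(m %*% x + 1),
                      parms = NULL, method = "lsoda",
                      rtol = 1e-10, atol = 1e-12)
  expect_lt(max(abs(traj$states - t(ode[, -1]))), 1e-6)
})

test_that("steady state solves the linear system and is the long-time limit", {
  set.seed(4)
  a <- matrix(stats::rexp(49) * (stats::runif(49) < 0.5), 7, 7)
  diag(a) <- 0
  rho <- choose_rho(a)
  xss <- consensus_steady_state(a, rho = rho)
  expect_lt(max(abs((a - rho * diag(7)) %*% xss + 1)), 1e-10)
  t_long <- 10 * settling_time(a, rho = rho)
  traj <- consensus_trajectories(a, rho = rho, times = c(0, t_long))
  expect_lt(max(abs(traj$states[, 2] - xss)), 1e-6)
})

test_that("equitable clusters share consensus trajectories exactly", {
  g <- planted_study_network(seed = 1)
  traj <- consensus_trajectories(g$network)
  spreads <- cluster_spread(traj, g$partition)
  expect_lt(max(spreads), 1e-10)
  xss <- consensus_steady_state(g$network)
  expect_lt(max(abs(tapply(xss, g$partition$assignment, max) -
                    tapply(xss, g$partition$assignment, min))), 1e-10)
})

test_that("settling time follows -4 / Lambda", {
  expect_equal(settling_time(matrix(0, 4, 4), rho = 1), 4.0)
  set.seed(5)
  a <- matrix(stats::rexp(36) * (stats::runif(36) < 0.5), 6, 6)
  diag(a) <- 0
  expect_equal(settling_time(a, rho = choose_rho(a, margin = 1)), 4.0,
               tolerance = 1e-9)
  expect_error(settling_time(a, rho = 0), "Hurwitz")
})

test_that("uncoupled oscillators with equal starts stay identical", {
  a <- matrix(0, 3, 3)
  x0 <- matrix(rep(c(0.3, -0.2, 0.1), each = 3), 3, 3)
  traj <- simulate_rossler(a, gamma = 0, x0 = x0, t_max = 20, dt = 0.01)
  x <- dyncomm:::traj_component(traj, 1)
  expect_lt(max(abs(x[1, ] - x[2, ])), 1e-13)
  expect_lt(max(abs(x[1, ] - x[3, ])), 1e-13)
  # chaotic, not fixed: the trajectory actually moves
  expect_gt(diff(range(x[1, ])), 1)
})

test_that("cluster-identical starts stay synchronized over a short horizon", {
  g <- planted_study_network(seed = 1, sizes = small_sizes)
  set.seed(7)
  ics <- matrix(stats::runif(15, -1, 1), 5, 3)
  x0 <- ics[g$partition$assignment, ]
  traj <- simulate_rossler(g$network, x0 = x0, t_max = 60, dt = 0.01)
  expect_lt(max(cluster_spread(traj, g$partition)), 1e-6)
  groups <- synchronized_groups(traj, tol = 1e-6)
  expect_equal(groups$k, 5)
  expect_partition_equal(groups, g$partition)
})

test_that("halving the step changes a short trajectory only marginally", {
  g <- planted_study_network(seed = 2, sizes = c(3, 3))
  x0 <- matrix(c(0.2, -0.1, 0.05), 6, 3, byrow = TRUE)
  t1 <- simulate_rossler(g$network, x0 = x0, t_max = 5, dt = 0.02)
  t2 <- simulate_rossler(g$network, x0 = x0, t_max = 5, dt = 0.01)
  x1 <- dyncomm:::traj_component(t1, 1)
  x2 <- dyncomm:::traj_component(t2, 1)
  x2_on_coarse_grid <- x2[, seq(1, ncol(x2), by = 2)]
  expect_lt(max(abs(x1 - x2_on_coarse_grid)), 1e-7)
})

test_that("cluster spread rises with the perturbation magnitude", {
  g <- planted_study_network(seed = 3, sizes = c(4, 3, 3))
  wins <- 0L
  for (s in 1:5) {
    nets <- c(list(g$network),
              lapply(c(0.1, 1), function(eps)
                perturb(g$network, eps, "type1", seed = s)))
    # one damping stabilizing all three networks, for comparability
    rho <- max(vapply(nets, choose_rho, numeric(1)))
    times <- seq(0, settling_time(nets[[1]], rho), length.out = 50)
    sp <- vapply(nets, function(net) {
      max(cluster_spread(consensus_trajectories(net, rho = rho,
                                                times = times),
                         g$partition))
    }, numeric(1))
    wins <- wins + (sp[1] < sp[2] && sp[2] < sp[3])
  }
  expect_gte(wins, 4L)  # monotone for (at least) the vast majority of seeds
})
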