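test_that("stationary covariance solves the Lyapunov equation", {
  # 1-D linear relaxation: variance d / lambda
  net1 <- bipartite_network(matrix(0, 1, 1))
  # analytic scalar check through the internal solver route: A = -lambda
  lam <- 0.7; d <- 0.01
  S <- ecoscape:::lyapunov_stationary(matrix(-lam, 1, 1), d)
  expect_equal(S[1, 1], d / lam, tolerance = 1e-12)
  # A = -I in any dimension gives d * I
  S4 <- ecoscape:::lyapunov_stationary(-diag(4), 0.02)
  expect_equal(S4, 0.02 * diag(4), tolerance = 1e-12)

  # random stable 4x4 systems: Lyapunov residual and covariance-ODE oracle
  set.seed(11)
  for (r in 1:5) {
    A <- matrix(rnorm(16), 4)
    A <- A - (max(Re(eigen(A)$values)) + 0.5) * diag(4)  # force stability
    expect_lt(max(Re(eigen(A)$values)), 0)
    S <- ecoscape:::lyapunov_stationary(A, 0.01)
    expect_lt(max(abs(S %*% t(A) + A %*% S + 2 * 0.01 * diag(4))), 1e-8)
    # independent oracle: integrate dS/dt = S A' + A S + 2 d I to steady state
    ode_rhs <- function(t, y, p) {
      Sm <- matrix(y, 4, 4)
      list(as.vector(Sm %*% t(A) + A %*% Sm + 2 * 0.01 * diag(4)))
    }
    sol <- deSolve::ode(as.vector(diag(4) * 0), c(0, 200), ode_rhs, NULL,
                        method = "lsoda", rtol = 1e-10, atol = 1e-12)
    S_ode <- matrix(sol[nrow(sol), -1], 4, 4)
    expect_equal(S, (S_ode + t(S_ode)) / 2, tolerance = 1e-7)
  }

  # an unstable state is rejected
  fx <- fixture_system()
  # the extinction state is unstable (plants invade at rate alpha)
  expect_error(stationary_moments(rep(0, 30), fx$net, fx$params),
               "not linearly stable")
})

test_that("Monte-Carlo Langevin covariance matches the Lyapunov solution", {
  # 2-D linear system simulated with the generic stepper
  A <- matrix(c(-1.2, 0.3, -0.2, -0.8), 2, 2, byrow = TRUE)
  d <- 0.05
  S <- ecoscape:::lyapunov_stationary(A, d)
  tr <- euler_maruyama(c(0, 0), function(x) as.numeric(A %*% x),
                       noise_spec(d), dt = 0.005, t_end = 4000, seed = 42,
                       record_every = 20)
  emp <- cov(tr$states[-(1:500), ])
  expect_lt(max(abs(emp - S)) / max(abs(S)), 0.15)
})

test_that("mixture density and potential behave like a proper density", {
  fx <- fixture_system()
  att <- fixture_attractors()
  mix <- tme_landscape(att, d = 0.005)
  # single component: potential at the mode equals the Gaussian mode value
  c1 <- stationary_moments(att$states[1, ], fx$net, fx$params, d = 0.005)
  single <- assemble_mixture(list(c1), 1)
  N <- 30
  U_mode <- 0.5 * N * log(2 * pi) +
    0.5 * as.numeric(determinant(c1$cov, logarithm = TRUE)$modulus)
  expect_equal(unname(mixture_potential(single, c1$mean)), U_mode,
               tolerance = 1e-10)
  # weights must sum to one
  expect_error(assemble_mixture(list(c1, c1), c(0.5, 0.6)), "sum to 1")
  # mixture density is positive and integrates to ~1 in a 2-D toy
  m1 <- list(mean = c(0, 0), cov = diag(2) * 0.2, d = 0.01)
  m2 <- list(mean = c(2, 1), cov = diag(2) * 0.1, d = 0.01)
  class(m1) <- class(m2) <- "gaussian_component"
  mx <- assemble_mixture(list(m1, m2), c(0.3, 0.7))
  gr <- seq(-6, 8, length.out = 141)
  h <- diff(gr[1:2])
  dens <- matrix(mixture_density(mx, as.matrix(expand.grid(gr, gr))),
                 141, 141)
  expect_equal(sum(dens) * h^2, 1, tolerance = 1e-3)
  # two well-separated equal components give equal-depth minima
  expect_equal(mixture_potential(mx, m1$mean) -
                 mixture_potential(assemble_mixture(list(m1, m2),
                                                    c(0.5, 0.5)), m1$mean),
               log(0.5 / 0.3), tolerance = 1e-6)
})

test_that("bipartite reduction reproduces exact mixture moments", {
  fx <- fixture_system()
  att <- fixture_attractors()
  mix <- tme_landscape(att, d = 0.005)
  # M = 1 collapses to the component covariance block
  c1 <- stationary_moments(att$states[1, ], fx$net, fx$params, d = 0.005)
  single <- assemble_mixture(list(c1), 1)
  bm <- ecoscape:::mixture_block_moments(single, 1:17)
  expect_equal(bm$cov, (c1$cov[1:17, 1:17] + t(c1$cov[1:17, 1:17])) / 2,
               tolerance = 1e-12)
  # two identical components with any weights reduce like M = 1
  twin <- assemble_mixture(list(c1, c1), c(0.3, 0.7))
  expect_equal(ecoscape:::mixture_block_moments(twin, 1:17)$cov, bm$cov,
               tolerance = 1e-12)
  # sampling oracle: moment formula equals empirical moments of samples
  set.seed(5)
  m1 <- c(0, 0); m2 <- c(3, 1)
  C1 <- matrix(c(0.3, 0.1, 0.1, 0.2), 2)
  C2 <- matrix(c(0.15, -0.05, -0.05, 0.25), 2)
  w <- c(0.4, 0.6)
  n <- 2e5
  pick <- runif(n) < w[1]
  L1 <- chol(C1); L2 <- chol(C2)
  Z <- matrix(rnorm(2 * n), n, 2)
  X <- ifelse(matrix(pick, n, 2),
              Z %*% L1 + matrix(m1, n, 2, byrow = TRUE),
              Z %*% L2 + matrix(m2, n, 2, byrow = TRUE))
  mock <- list(means = rbind(m1, m2), covs = list(C1, C2), weights = w,
               labels = c(NA, NA), d = 0.01)
  class(mock) <- "gaussian_mixture"
  bm2 <- ecoscape:::mixture_block_moments(mock, 1:2)
  expect_equal(unname(bm2$mean), unname(colMeans(X)), tolerance = 0.02)
  expect_equal(unname(bm2$cov), unname(cov(X)), tolerance = 0.05)
})

test_that("the reduced landscape of one isotropic component is a bowl", {
  m <- list(mean = c(rep(1, 2), rep(2, 2)), cov = diag(4) * 0.1, d = 0.01)
  class(m) <- "gaussian_component"
  mix <- assemble_mixture(list(m), 1)
  net <- bipartite_network(matrix(1, 2, 2))
  proj <- reduce_bipartite(mix, net)
  red <- reduced_landscape(mix, proj, n_grid = 81)
  # U - min(U) is exactly quadratic in the distance from the projected mean
  mu_z <- as.numeric(t(proj$W) %*% m$mean)
  i0 <- which.min(abs(red$z1 - mu_z[1]))
  j0 <- which.min(abs(red$z2 - mu_z[2]))
  # projected covariance is 0.1 * I (unit projection vectors)
  dz <- red$z1[i0 + 10] - mu_z[1]
  expect_equal(red$U[i0 + 10, j0] - red$U[i0, j0], dz^2 / (2 * 0.1),
               tolerance = 1e-6)
  # landscape sign convention puts the single (high) component at the top
  expect_gte(sum(proj$w1_P), 0)
})

test_that("saddle search matches symmetry and a fine-grid oracle", {
  net <- bipartite_network(matrix(1, 2, 2))
  mk <- function(mu, s = 0.05) {
    m <- list(mean = mu, cov = diag(4) * s, d = 0.01)
    class(m) <- "gaussian_component"
    m
  }
  lo <- mk(rep(0.2, 4)); hi <- mk(rep(1.8, 4))
  mix <- assemble_mixture(list(lo, hi), c(0.5, 0.5),
                          labels = c("low", "high"))
  proj <- reduce_bipartite(mix, net)
  red <- reduced_landscape(mix, proj, n_grid = 101)
  s <- find_saddle(red, 1, 2)
  mid <- as.numeric(t(proj$W) %*% ((lo$mean + hi$mean) / 2))
  # symmetric equal-weight case: saddle at the midpoint, RBH = 0
  expect_lt(max(abs(s$z_saddle - mid)), 0.06)
  br <- barrier_report(red)
  expect_equal(br$RBH_ij[1], 0, tolerance = 1e-6)
  expect_false(br$merged[1])

  # asymmetric weights: the heavier basin is deeper; fine-grid oracle
  mixa <- assemble_mixture(list(lo, hi), c(0.8, 0.2),
                           labels = c("low", "high"))
  reda <- reduced_landscape(mixa, proj, n_grid = 101)
  bra <- barrier_report(reda, pairs = list(c(1, 2)))
  expect_gt(bra$BH_i[1], bra$BH_j[1])  # leaving the heavy basin costs more
  expect_lt(bra$RBH_ij[1], 0)
  red4 <- reduced_landscape(mixa, proj, n_grid = 401)
  bra4 <- barrier_report(red4, pairs = list(c(1, 2)))
  # saddle level agrees with the 4x-resolution oracle
  expect_lt(abs(bra$U_saddle[1] - bra4$U_saddle[1]), 0.1)
})

test_that("potential is invariant to in-block species relabeling", {
  fx <- fixture_system()
  att <- fixture_attractors()
  mix <- tme_landscape(att, d = 0.005)
  proj <- reduce_bipartite(mix, fx$net)
  red <- reduced_landscape(mix, proj, n_grid = 61)
  # permute plants consistently in states and covariances
  perm <- c(sample(1:17), 18:30)
  set.seed(1)
  mixp <- mix
  mixp$means <- mix$means[, perm]
  mixp$covs <- lapply(mix$covs, function(C) C[perm, perm])
  projp <- proj
  projp$w1_P <- proj$w1_P[perm[1:17]]
  projp$W <- proj$W[perm, ]
  redp <- reduced_landscape(mixp, projp, n_grid = 61,
                            z1_range = range(red$z1),
                            z2_range = range(red$z2))
  expect_equal(red$U, redp$U, tolerance = 1e-9)
})

test_that("landscape grid exports round-trip as delimited tables", {
  fx <- fixture_system()
  att <- fixture_attractors()
  mix <- tme_landscape(att, d = 0.005)
  proj <- reduce_bipartite(mix, fx$net)
  red <- reduced_landscape(mix, proj, n_grid = 21)
  f <- withr::local_tempfile(fileext = ".csv")
  write_landscape(red, f)
  tab <- read.csv(f)
  expect_equal(nrow(tab), 21 * 21)
  expect_equal(tab$U[1], red$U[1, 1])
})
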