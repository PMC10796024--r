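test_that("drift matches hand-expanded expressions", {
  # extinction is a fixed point without immigration
  net <- tiny_net()
  p <- model_params(mu_P = 0, mu_A = 0)
  expect_equal(glv_drift(rep(0, 5), net, p), rep(0, 5))

  # single plant with a disconnected pollinator: logistic equilibrium
  net1 <- bipartite_network(matrix(0, 1, 1))
  expect_equal(glv_drift(c(0.3, 0), net1, p)[1], 0)

  # 1 plant - 1 pollinator: symbolically expanded right-hand side
  net11 <- bipartite_network(matrix(1, 1, 1))
  pars <- model_params(alpha_P = 0.4, alpha_A = 0.25, beta_intra_P = 1.1,
                       beta_intra_A = 0.9, kappa = 0.8, gamma0 = 1.3,
                       delta = 0.5, h = 0.15, mu_P = 0.002, mu_A = 0.001)
  P <- 0.7; A <- 1.2; g <- 1.3  # degree 1 so gamma = gamma0
  hand <- c(0.4 * P - 1.1 * P^2 + P * g * A / (1 + 0.15 * g * A) + 0.002,
            0.25 * A - 0.8 * A - 0.9 * A^2 +
              A * g * P / (1 + 0.15 * g * P) + 0.001)
  expect_equal(glv_drift(c(P, A), net11, pars), hand, tolerance = 1e-12)

  # NaN input is an error, not silent propagation
  expect_error(glv_drift(c(NaN, 1), net11, pars), "non-finite")
})

test_that("analytic Jacobian agrees with central differences", {
  set.seed(3)
  net <- generate_network(6, 7, 0.4, heterogeneity = 0.8, seed = 21)
  p <- model_params(beta_inter_P = 0.02, beta_inter_A = 0.015)
  n <- 13
  for (r in 1:20) {
    x <- runif(n, 0, 2)
    J <- glv_jacobian(x, net, p)
    fd <- vapply(seq_len(n), function(j) {
      e <- rep(0, n); e[j] <- 1e-6
      (glv_drift(x + e, net, p) - glv_drift(x - e, net, p)) / 2e-6
    }, numeric(n))
    expect_lt(max(abs(J - fd)) / max(1, max(abs(J))), 1e-6)
  }
  # decoupled guilds with beta_inter = 0: cross entries of same guild are 0
  net0 <- bipartite_network(diag(2))
  p0 <- model_params(beta_inter_P = 0, beta_inter_A = 0)
  J0 <- glv_jacobian(runif(4), net0, p0)
  expect_equal(J0[1, 2], 0)   # plant 1 vs plant 2
  expect_equal(J0[3, 4], 0)   # pollinator 1 vs pollinator 2
})

test_that("a lone plant relaxes to its carrying capacity", {
  net <- bipartite_network(matrix(0, 1, 1))
  p <- model_params(mu_P = 0, mu_A = 0)
  att <- find_attractors(net, p, n_starts = 8, seed = 2)
  expect_equal(nrow(att$states), 1)
  expect_equal(unname(att$states[1, 1]), 0.3, tolerance = 1e-6)
  expect_equal(att$phi, 1)
  expect_equal(max(abs(glv_drift(att$states[1, ], net, p))), 0,
               tolerance = 1e-8)
})

test_that("the fixture network is tristable with verified attractors", {
  att <- fixture_attractors()
  fx <- fixture_system()
  expect_equal(att$scenario, "HIL")
  expect_setequal(att$labels, c("high", "intermediate", "low"))
  expect_equal(sum(att$phi), 1)
  # every reported attractor satisfies the residual and stability invariants
  for (i in seq_len(nrow(att$states))) {
    expect_lt(max(abs(glv_drift(att$states[i, ], fx$net, fx$params))), 1e-8)
    expect_lt(max(Re(att$spectra[[i]])), 0)
  }
  # the intermediate state keeps exactly one pollinator, the generalist
  ia <- fx$net$n_plants + seq_len(fx$net$n_pollinators)
  int <- att$states[att$labels == "intermediate", ia]
  expect_equal(sum(int >= 1e-3), 1)
  expect_equal(unname(which.max(int)), unname(which.max(pollinator_degrees(fx$net))))
  # low state: all pollinators extinct, plants rare but present
  low <- att$states[att$labels == "low", ]
  expect_true(all(low[ia] < 1e-3))
  expect_gt(sum(low[seq_len(17)] > 1e-3), 0)
})

test_that("attractor sets are stable under doubling the start count", {
  fx <- fixture_system()
  att1 <- fixture_attractors()
  att2 <- find_attractors(fx$net, fx$params, n_starts = 160, seed = 1,
                          x_hi = fx$x_hi)
  expect_equal(att2$scenario, "HIL")
  # same attractor states within the merge radius
  for (i in seq_len(nrow(att1$states))) {
    dmin <- min(apply(att2$states, 1, function(s)
      max(abs(s - att1$states[i, ]))))
    expect_lt(dmin, 1e-3)
  }
})

test_that("state classification follows the abundance ranking rules", {
  net <- tiny_net()  # 3 plants, 2 pollinators
  low <- c(0.3, 0.3, 0.3, 0, 0)
  high <- c(1, 1, 1, 0.9, 0.8)
  inter <- c(0.5, 0.5, 0.5, 0.4, 0)   # one of two pollinators alive
  expect_equal(classify_states(rbind(low, high, inter), net),
               c("low", "high", "intermediate"))
  # a single state with all species alive is high
  expect_equal(classify_state(high, net), "high")
  # all pollinators below threshold means low, whatever the plants do
  expect_equal(classify_state(c(2, 2, 2, 1e-4, 0), net), "low")
  # scenario coding
  expect_equal(scenario_code(c("high", "intermediate", "low")), "HIL")
  expect_equal(scenario_code("high"), "H")
  expect_equal(scenario_code(c("intermediate", "low")), "IL")
  expect_equal(scenario_code(c("high", "intermediate", "intermediate",
                               "low")), "T")
  expect_equal(scenario_code(c("high", "other")), "other")
})

test_that("removal census tabulates proportions that sum to one", {
  # a small monostable-high base network stays 100% H at fraction 0
  net <- generate_network(5, 6, 0.5, seed = 8)
  p <- model_params(kappa = 0.6)
  cs <- removal_census(net, p, fractions = c(0, 0.5), n_subnets = 6,
                       seed = 4, n_starts = 10)
  for (fr in unique(cs$fraction))
    expect_equal(sum(cs$proportion[cs$fraction == fr]), 1)
  expect_equal(cs$proportion[cs$fraction == 0 & cs$scenario == "H"], 1)
})

test_that("phase diagram recovers monostable limits", {
  fx <- fixture_system()
  # large kappa: pollinator decay dominates, low state everywhere
  pd <- phase_diagram(fx$net, fx$params, kappa_grid = c(5, 6),
                      gamma0_grid = c(0.9, 1.1), seed = 2, n_starts = 8,
                      x_hi = 1)
  expect_true(all(pd == "L"))
  # kappa = 0 with strong mutualism: a single high state on a small toy
  toy <- generate_network(3, 3, 0.8, seed = 5)
  pd2 <- phase_diagram(toy, model_params(), kappa_grid = 0,
                       gamma0_grid = 1.5, seed = 2, n_starts = 10)
  expect_equal(unname(as.vector(pd2)), "H")
  # determinism under the same seed
  expect_identical(pd, phase_diagram(fx$net, fx$params, c(5, 6),
                                     c(0.9, 1.1), seed = 2, n_starts = 8,
                                     x_hi = 1))
})

test_that("integrated trajectories stay non-negative", {
  fx <- fixture_system()
  tr <- simulate_langevin(fx$net, fx$params, rep(0.8, 30),
                          noise_spec(0), dt = 0.01, t_end = 50,
                          record_every = 10)
  expect_true(all(tr$states >= 0))
})
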