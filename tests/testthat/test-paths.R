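test_that("the action vanishes on deterministic trajectories", {
  # sample a trajectory of dx/dt = f and check S -> 0 as L grows
  f <- function(x) -0.8 * x
  S_of <- function(L) {
    tt <- seq(0, 5, length.out = L)
    nodes <- matrix(2 * exp(-0.8 * tt), ncol = 1)
    path_action(nodes, tt, f)
  }
  expect_lt(S_of(80), 1e-3)
  expect_lt(S_of(160), S_of(80))
  # zero-length segments are rejected
  expect_error(path_action(matrix(c(0, 1), 2), c(0, 0), f), "increasing")
})

test_that("the action gradient matches finite differences", {
  set.seed(8)
  f <- function(x) c(x[1] - x[1]^3 - 0.2 * x[2], -x[2] + 0.1 * x[1])
  jac <- function(x) matrix(c(1 - 3 * x[1]^2, -0.2, 0.1, -1), 2, 2,
                            byrow = TRUE)
  L <- 7
  nodes <- matrix(rnorm(2 * L), L, 2)
  times <- seq(0, 3, length.out = L)
  ag <- ecoscape:::action_with_grad(nodes, times, f, jac)
  for (k in 2:(L - 1)) for (j in 1:2) {
    e <- matrix(0, L, 2); e[k, j] <- 1e-6
    fd <- (path_action(nodes + e, times, f) -
             path_action(nodes - e, times, f)) / 2e-6
    expect_equal(ag$grad[k, j], fd, tolerance = 1e-5)
  }
})

test_that("double-well uphill action recovers the 2*DeltaV identity", {
  # gradient system f = -V' with V = x^4/4 - x^2/2: S(x=-1 -> 0) = 1/2
  p40 <- minimize_action(-1, 0, dw_f, dw_jac, L = 40, lower = -Inf)
  expect_lt(abs(p40$action - 0.5) / 0.5, 0.02)
  # richer discretization never increases the minimum (within optimizer tol)
  p20 <- minimize_action(-1, 0, dw_f, dw_jac, L = 20, lower = -Inf)
  expect_lt(p40$action, p20$action + 1e-3)
  # downhill costs essentially nothing; hence strong asymmetry
  down <- minimize_action(0.05, 1, dw_f, dw_jac, L = 20, lower = -Inf)
  expect_lt(down$action, 0.01)
  # degenerate request: identical endpoints
  p0 <- minimize_action(1, 1, dw_f, dw_jac, L = 10)
  expect_equal(p0$action, 0)
})

test_that("network paths respect non-negativity and direct <= indirect", {
  fx <- fixture_system()
  att <- fixture_attractors()
  xh <- att$states[att$labels == "high", ]
  xi <- att$states[att$labels == "intermediate", ]
  xl <- att$states[att$labels == "low", ]
  direct <- transition_path(fx$net, fx$params, xh, xl, L = 12,
                            T_schedule = c(30, 60))
  expect_true(all(direct$nodes >= 0))
  expect_gte(direct$action, 0)
  indir <- indirect_path(fx$net, fx$params, xh, xi, xl, L = 12,
                         T_schedule = c(30, 60))
  expect_true(all(indir$nodes >= 0))
  expect_equal(indir$action, indir$legs[[1]]$action + indir$legs[[2]]$action)
  # collapse paths go through the intermediate state: the direct and
  # via-intermediate high->low routes nearly coincide, while the recovery
  # routes differ much more (compare the squared path distances)
  d_lh <- transition_path(fx$net, fx$params, xl, xh, L = 12,
                          T_schedule = c(30, 60))
  i_lh <- indirect_path(fx$net, fx$params, xl, xi, xh, L = 12,
                        T_schedule = c(30, 60))
  pd_hl <- path_distance(direct, indir, L = 12)
  pd_lh <- path_distance(d_lh, i_lh, L = 12)
  expect_lt(pd_hl, pd_lh)
  hm <- normalize_path_heatmap(direct)
  expect_true(all(is.finite(hm)) && max(hm) <= 1 && min(hm) >= 0)
  .cache$paths <- list(direct = direct, indirect = indir)
})

test_that("a waypoint on the optimal route adds nothing to the action", {
  # 1-D tilted well: the direct lo -> hi optimum passes through the saddle,
  # so the concatenated legs reproduce the direct minimum
  f <- function(x) x - x^3 - 0.15
  jac <- function(x) matrix(1 - 3 * x^2, 1, 1)
  roots <- sort(Re(polyroot(c(-0.15, 1, 0, -1))))
  S_direct <- minimize_action(roots[1], roots[3], f, jac, L = 40,
                              lower = -Inf)$action
  S_legs <- minimize_action(roots[1], roots[2], f, jac, L = 20,
                            lower = -Inf)$action +
    minimize_action(roots[2], roots[3], f, jac, L = 20,
                    lower = -Inf)$action
  expect_equal(S_direct, S_legs, tolerance = 0.05)
})

test_that("path distance is a symmetric squared-Euclidean sum", {
  # hand-computed example: two 3-node, 2-species paths differing by (1, 0)
  a <- structure(list(nodes = rbind(c(0, 0), c(1, 1), c(2, 2)),
                      times = 0:2, action = 0), class = "transition_path")
  b <- a
  b$nodes[2, ] <- b$nodes[2, ] + c(1, 0)
  expect_equal(path_distance(a, b, L = 3), 1)
  expect_equal(path_distance(b, a, L = 3), path_distance(a, b, L = 3))
  expect_equal(path_distance(a, a, L = 3), 0)
})

test_that("forward and backward actions differ in a tilted double well", {
  # V(x) = x^4/4 - x^2/2 + 0.15 x: the +0.15x tilt deepens the LEFT basin
  f <- function(x) x - x^3 - 0.15
  jac <- function(x) matrix(1 - 3 * x^2, 1, 1)
  roots <- sort(Re(polyroot(c(-0.15, 1, 0, -1))))
  lo <- roots[1]; saddle <- roots[2]; hi <- roots[3]
  V <- function(x) x^4 / 4 - x^2 / 2 + 0.15 * x
  S_lr <- minimize_action(lo, saddle, f, jac, L = 30, lower = -Inf)$action
  S_rl <- minimize_action(hi, saddle, f, jac, L = 30, lower = -Inf)$action
  # gradient identity oracle on each uphill leg
  expect_equal(S_lr, 2 * (V(saddle) - V(lo)), tolerance = 0.03)
  expect_equal(S_rl, 2 * (V(saddle) - V(hi)), tolerance = 0.03)
  # the deeper (left) basin is harder to leave
  expect_gt(S_lr, S_rl)
})

test_that("heatmap normalization conventions", {
  nodes <- cbind(seq(0, 2, length.out = 5), rep(0.7, 5),
                 c(0, 1, 0.5, 1.5, 2))
  hm <- normalize_path_heatmap(nodes)
  expect_equal(hm[, 1], seq(0, 1, length.out = 5))  # monotone -> 0..1
  expect_equal(hm[, 2], rep(0, 5))                  # constant -> all zeros
  # invariance under affine rescaling of raw abundances
  expect_equal(normalize_path_heatmap(nodes * 3 + 1), hm)
})
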