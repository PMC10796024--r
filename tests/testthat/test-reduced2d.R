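random_rp <- function() {
  reduced_params(alpha = runif(1, 0.1, 0.6), beta = runif(1, 0.5, 2),
                 kappa = runif(1, 0.2, 2.5), h = runif(1, 0.05, 0.5),
                 gammaP_mean = runif(1, 0.2, 3),
                 gammaA_mean = runif(1, 0.2, 3))
}

test_that("closed-form fixed points are exact roots of the 2-D drift", {
  set.seed(17)
  for (r in 1:300) {
    rp <- random_rp()
    fp <- fixed_points_2d(rp)
    for (i in seq_len(nrow(fp)))
      expect_lt(max(abs(ecoscape:::drift_2d(c(fp$P[i], fp$A[i]), rp))),
                1e-10)
  }
})

test_that("closed-form stability always agrees with numeric eigenvalues", {
  set.seed(23)
  n_stable_max <- 0
  for (r in 1:1000) {
    rp <- random_rp()
    fp <- fixed_points_2d(rp)
    for (i in seq_len(nrow(fp))) {
      # stability_2d errors on any closed-form/numeric disagreement
      s <- stability_2d(fp$P[i], fp$A[i], fp$kind[i], rp)
      expect_type(s$stable, "logical")
    }
    n_stable_max <- max(n_stable_max, sum(fp$stable))
  }
  # the reduced model never supports three stable states: no intermediate
  expect_lte(n_stable_max, 2)
})

test_that("the pollinator-free state stabilizes at the printed threshold", {
  # alpha = 0.3, beta = 1, <gammaA> = 1, h = 0.2: threshold 0.3 + 0.3/1.06
  thr <- 0.3 + 0.3 / 1.06
  rp1 <- reduced_params(alpha = 0.3, beta = 1, gammaA_mean = 1, h = 0.2,
                        kappa = thr - 1e-3)
  rp2 <- reduced_params(alpha = 0.3, beta = 1, gammaA_mean = 1, h = 0.2,
                        kappa = thr + 1e-3)
  expect_false(stability_2d(0.3, 0, "pollinator_free", rp1)$stable)
  expect_true(stability_2d(0.3, 0, "pollinator_free", rp2)$stable)
  # origin and plant-free point are always unstable for positive alpha
  set.seed(31)
  for (r in 1:50) {
    rp <- random_rp()
    fp <- fixed_points_2d(rp)
    expect_false(any(fp$stable[fp$kind %in% c("origin", "plant_free")]))
    # upper interior branch stable, lower unstable, whenever both exist
    if (all(c("interior_A4", "interior_A5") %in% fp$kind)) {
      expect_true(fp$stable[fp$kind == "interior_A5"])
      expect_false(fp$stable[fp$kind == "interior_A4"])
    }
  }
})

test_that("interior roots match a dense-grid numeric root finder", {
  set.seed(41)
  for (r in 1:150) {
    rp <- random_rp()
    fp <- fixed_points_2d(rp)
    interior <- fp[grepl("interior", fp$kind), , drop = FALSE]
    # Newton from a dense positive grid; collect distinct interior roots
    found <- list()
    for (P0 in seq(0.05, 3, length.out = 7))
      for (A0 in seq(0.05, 3, length.out = 7)) {
        x <- c(P0, A0)
        for (it in 1:80) {
          fx <- ecoscape:::drift_2d(x, rp)
          if (max(abs(fx)) < 1e-12) break
          J <- ecoscape:::jacobian_2d(x, rp)
          st <- tryCatch(solve(J, -fx), error = function(e) NULL)
          if (is.null(st)) break
          x <- x + st
          if (any(!is.finite(x)) || max(abs(x)) > 1e4) break
        }
        if (all(is.finite(x)) && max(abs(ecoscape:::drift_2d(x, rp))) < 1e-10 &&
            all(x > 1e-6)) {
          dup <- any(vapply(found, function(y) max(abs(y - x)) < 1e-6, TRUE))
          if (!dup) found[[length(found) + 1]] <- x
        }
      }
    # every numerically found interior equilibrium appears in the closed form
    for (x in found) {
      dmin <- if (nrow(interior)) min(abs(interior$A - x[2])) else Inf
      expect_lt(dmin, 1e-6)
    }
  }
})

test_that("the kappa bifurcation exhibits the fold and the root-count path", {
  rp <- reduced_params(alpha = 0.3, beta = 1, h = 0.2,
                       gammaP_mean = 2.5, gammaA_mean = 2.5)
  bif <- kappa_bifurcation_2d(rp, c(0.3, 2.5), n = 221)
  expect_false(is.na(bif$kappa_saddle_node))
  # discriminant vanishes at the fold and the double root is positive
  rpk <- rp; rpk$kappa <- bif$kappa_saddle_node
  q <- ecoscape:::interior_quadratic(rpk)
  expect_lt(abs(q[["q2"]]^2 - 4 * q[["q1"]] * q[["q3"]]), 1e-8)
  expect_gt(bif$A_saddle_node, 0)
  # positive-root count passes 1 -> 2 -> 0 on the grid, with the double
  # root (count collapsing to a single value) exactly at the fold
  runs <- rle(bif$n_positive_interior)$values
  expect_equal(runs[runs != 0], c(1, 2))
  expect_equal(rev(runs)[1], 0)
  rpk$kappa <- bif$kappa_saddle_node - 1e-6  # just inside the fold
  fpk <- fixed_points_2d(rpk)
  ints <- fpk$A[grepl("interior", fpk$kind)]
  expect_equal(length(ints), 2)
  expect_lt(diff(range(ints)), 0.05)  # branches nearly merged
  expect_equal(bif$A_saddle_node, mean(ints), tolerance = 1e-2)
})

test_that("closed forms at mu = 0 are continuous against small immigration", {
  rp <- reduced_params(alpha = 0.3, beta = 1, h = 0.2, kappa = 1.2,
                       gammaP_mean = 2.5, gammaA_mean = 2.5)
  fp <- fixed_points_2d(rp)
  hi <- fp[fp$kind == "interior_A5", ]
  rp_mu <- rp; rp_mu$mu <- 1e-3
  x <- c(hi$P, hi$A)
  for (it in 1:60) {
    fx <- ecoscape:::drift_2d(x, rp_mu)
    if (max(abs(fx)) < 1e-13) break
    x <- x + solve(ecoscape:::jacobian_2d(x, rp_mu), -fx)
  }
  expect_lt(max(abs(x - c(hi$P, hi$A))), 0.01)
})

test_that("network aggregation produces the effective mean strengths", {
  net <- tiny_net()
  p <- model_params(gamma0 = 1, delta = 0.5)
  mg <- mean_gamma(net, p)
  g <- build_gamma(net, p)
  expect_equal(mg$gammaP_mean, mean(rowSums(g$gamma_PA)))
  expect_equal(mg$gammaA_mean, mean(rowSums(g$gamma_AP)))
  expect_gt(mg$gammaP_mean, 0)
})
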