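# Closed-form analysis of the two-dimensional mean-field reduction:
# fixed points from the interior quadratic, stability conditions, and the
# saddle-node along kappa. The headline property of this module is that
# the 2-D model supports at most two stable states (high and low) and
# never an intermediate one, which motivates the multidimensional model.

#' Parameters of the 2-D mean-field model
#'
#' The reduction collapses the plant and pollinator guilds to aggregates
#' `P'` and `A'` with effective mutualistic strengths `gammaP_mean`
#' (`<gammaP>`, gain of plants from pollinators) and `gammaA_mean`
#' (`<gammaA>`).
#'
#' @param alpha,beta,kappa,h,mu scalar rates as in the full model.
#' @param gammaP_mean,gammaA_mean effective mutualistic strengths.
#' @return An object of class `reduced_params`.
#' @export
reduced_params <- function(alpha = 0.3, beta = 1, kappa = 1.07, h = 0.2,
                           mu = 0, gammaP_mean = 1, gammaA_mean = 1) {
  p <- list(alpha = alpha, beta = beta, kappa = kappa, h = h, mu = mu,
            gammaP_mean = gammaP_mean, gammaA_mean = gammaA_mean)
  for (nm in names(p))
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || p[[nm]] < 0)
      stop("reduced parameter '", nm, "' must be a non-negative scalar",
           call. = FALSE)
  structure(p, class = "reduced_params")
}

#' Effective mean mutualistic strengths of a network
#'
#' Aggregates the degree-dependent strength matrices of [build_gamma()]
#' into the two effective strengths of the 2-D reduction: the mean over
#' species of the row sums of the respective gamma matrix (the average
#' total per-capita gain of a plant from all pollinators, and vice versa).
#'
#' @inheritParams build_gamma
#' @return Named list with `gammaP_mean` and `gammaA_mean`.
#' @export
mean_gamma <- function(net, params) {
  g <- build_gamma(net, params)
  list(gammaP_mean = mean(rowSums(g$gamma_PA)),
       gammaA_mean = mean(rowSums(g$gamma_AP)))
}

# Drift of the 2-D model.
drift_2d <- function(x, rp) {
  P <- x[1]; A <- x[2]
  gP <- rp$gammaP_mean; gA <- rp$gammaA_mean
  c(rp$alpha * P - rp$beta * P^2 +
      gP * A / (1 + rp$h * gP * A) * P + rp$mu,
    rp$alpha * A - rp$beta * A^2 - rp$kappa * A +
      gA * P / (1 + rp$h * gA * P) * A + rp$mu)
}

jacobian_2d <- function(x, rp) {
  P <- x[1]; A <- x[2]
  gP <- rp$gammaP_mean; gA <- rp$gammaA_mean
  bP <- gP * A / (1 + rp$h * gP * A)
  bA <- gA * P / (1 + rp$h * gA * P)
  matrix(c(rp$alpha - 2 * rp$beta * P + bP,
           P * gP / (1 + rp$h * gP * A)^2,
           A * gA / (1 + rp$h * gA * P)^2,
           rp$alpha - 2 * rp$beta * A - rp$kappa + bA),
         2, 2, byrow = TRUE)
}

# Coefficients of the interior quadratic q1 A'^2 + q2 A' + q3 = 0
# (mu ~ 0 closed form).
interior_quadratic <- function(rp) {
  a <- rp$alpha; b <- rp$beta; k <- rp$kappa; h <- rp$h
  gP <- rp$gammaP_mean; gA <- rp$gammaA_mean
  q1 <- b^2 * h * gP + h^2 * gP * gA * a * b + h * b * gP * gA
  q2 <- b * (h * gA * a + b) - a * h * gP * gA - gP * gA +
    (k - a) * (h * gP * b + h^2 * gP * gA * a + h * gP * gA)
  q3 <- (k - a) * (h * gA * a + b) - gA * a
  c(q1 = q1, q2 = q2, q3 = q3)
}

interior_P_from_A <- function(A, rp) {
  gP <- rp$gammaP_mean
  (rp$alpha + gP * A / (1 + rp$h * gP * A)) / rp$beta
}

#' Fixed points of the 2-D mean-field model
#'
#' Closed-form stationary points under `mu ~ 0`: the origin, the
#' plant-free point `(0, (alpha - kappa) / beta)`, the pollinator-free
#' (low) point `(alpha / beta, 0)`, and the interior roots of the
#' quadratic `q1 A'^2 + q2 A' + q3 = 0` with `P'` recovered from `A'`.
#' Complex or negative interior roots are excluded from the returned set
#' but reported in the `diagnostics` attribute together with the
#' discriminant.
#'
#' @param rp a [reduced_params()] (its `mu` is ignored in the closed
#'   forms; keep it near 0).
#' @return A data frame of class `fixed_points_2d` with columns `P`, `A`,
#'   `kind` (`origin`, `plant_free`, `pollinator_free`, `interior_A4`,
#'   `interior_A5`), `stable`, `eig1`, `eig2` (real parts).
#' @export
fixed_points_2d <- function(rp) {
  stopifnot(inherits(rp, "reduced_params"))
  q <- interior_quadratic(rp)
  disc <- q[["q2"]]^2 - 4 * q[["q1"]] * q[["q3"]]
  pts <- list(
    c(P = 0, A = 0, kind = "origin"),
    c(P = 0, A = (rp$alpha - rp$kappa) / rp$beta, kind = "plant_free"),
    c(P = rp$alpha / rp$beta, A = 0, kind = "pollinator_free"))
  roots <- c()
  if (abs(q[["q1"]]) < 1e-14) {
    if (abs(q[["q2"]]) > 1e-14) roots <- -q[["q3"]] / q[["q2"]]
  } else if (disc >= 0) {
    roots <- sort((-q[["q2"]] + c(-1, 1) * sqrt(disc)) / (2 * q[["q1"]]))
  }
  all_roots <- roots
  kinds <- if (length(roots) == 2) c("interior_A4", "interior_A5")
           else rep("interior_A5", length(roots))
  for (i in seq_along(roots)) {
    if (roots[i] <= 0) next
    pts[[length(pts) + 1]] <- c(P = interior_P_from_A(roots[i], rp),
                                A = roots[i], kind = kinds[i])
  }
  rows <- lapply(pts, function(pt) {
    x <- as.numeric(pt[c("P", "A")])
    if (any(x < 0)) return(NULL)  # drop e.g. plant-free with negative A
    ev <- eigen(jacobian_2d(x, rp), only.values = TRUE)$values
    data.frame(P = x[1], A = x[2], kind = pt[["kind"]],
               stable = max(Re(ev)) < 0,
               eig1 = Re(ev[1]), eig2 = Re(ev[2]))
  })
  out <- do.call(rbind, rows)
  attr(out, "diagnostics") <- list(quadratic = q, discriminant = disc,
                                   roots = all_roots)
  class(out) <- c("fixed_points_2d", class(out))
  out
}

# Closed-form stability criteria (mu ~ 0). Returns NA when the criterion
# does not apply to the kind.
closed_form_stable <- function(P, A, kind, rp) {
  a <- rp$alpha; b <- rp$beta; k <- rp$kappa; h <- rp$h
  gP <- rp$gammaP_mean; gA <- rp$gammaA_mean
  switch(kind,
    origin = FALSE,
    plant_free = FALSE,
    pollinator_free = k > a + gA * (a / b) / (1 + h * gA * (a / b)),
    interior_A4 = ,
    interior_A5 = {
      p1 <- (b * h * gP + h^2 * gP * gA * a + h * gP * gA)^2
      p2 <- 2 * (h * gP * b + h^2 * gP * gA * a + h * gP * gA) *
        (b + h * gA * a)
      p3 <- (h * gA * a + b)^2 - gP * gA
      p1 * A^2 + p2 * A + p3 > 0
    },
    NA)
}

#' Stability of a 2-D fixed point: closed form vs numeric
#'
#' Evaluates both the closed-form stability criterion (invasion eigenvalue
#' for the pollinator-free point; the interior quadratic criterion
#' `p1 A'^2 + p2 A' + p3 > 0` for interior points; always-unstable for the
#' origin and the plant-free point) and the numeric Jacobian eigenvalues,
#' and errors if the two verdicts disagree away from the stability
#' boundary.
#'
#' @param P,A fixed-point coordinates.
#' @param kind one of the kinds of [fixed_points_2d()].
#' @param rp a [reduced_params()].
#' @param boundary_tol spectral-abscissa half-width treated as borderline
#'   (no consistency check there).
#' @return List with `stable`, `eigenvalues`, `closed_form`.
#' @export
stability_2d <- function(P, A, kind, rp, boundary_tol = 1e-8) {
  ev <- eigen(jacobian_2d(c(P, A), rp), only.values = TRUE)$values
  num <- max(Re(ev)) < 0
  cf <- closed_form_stable(P, A, kind, rp)
  if (!is.na(cf) && abs(max(Re(ev))) > boundary_tol && cf != num)
    stop(sprintf(
      "closed-form and numeric stability disagree for %s at (%.4g, %.4g)",
      kind, P, A), call. = FALSE)
  list(stable = num, eigenvalues = ev, closed_form = cf)
}

#' Bifurcation structure of the 2-D model along kappa
#'
#' Tracks the fixed points over a kappa grid, counts positive interior
#' roots (the pattern 1 -> 2 -> 1 -> 0 brackets the multistable window),
#' and locates the saddle-node kappa where the discriminant of the
#' interior quadratic vanishes. Of the two discriminant roots in kappa the
#' one whose double root `A' = -q2 / (2 q1)` is positive is the
#' saddle-node; the other corresponds to a negative `A'` and is discarded.
#'
#' @param rp a [reduced_params()]; its `kappa` is ignored.
#' @param kappa_range length-2 range to scan.
#' @param n grid resolution (default 201).
#' @return A list of class `kappa_bifurcation`: data frame `branches`
#'   (`kappa`, `P`, `A`, `kind`, `stable`), integer vector
#'   `n_positive_interior` per grid point, `kappa_saddle_node` (`NA` if
#'   no sign change in range), and `A_saddle_node`.
#' @export
kappa_bifurcation_2d <- function(rp, kappa_range, n = 201) {
  kgrid <- seq(kappa_range[1], kappa_range[2], length.out = n)
  branches <- list()
  npos <- integer(n)
  for (i in seq_len(n)) {
    rpk <- rp; rpk$kappa <- kgrid[i]
    fp <- fixed_points_2d(rpk)
    fp$kappa <- kgrid[i]
    branches[[i]] <- fp[, c("kappa", "P", "A", "kind", "stable")]
    npos[i] <- sum(grepl("interior", fp$kind) & fp$A > 0)
  }
  disc_at <- function(k) {
    rpk <- rp; rpk$kappa <- k
    q <- interior_quadratic(rpk)
    q[["q2"]]^2 - 4 * q[["q1"]] * q[["q3"]]
  }
  dvals <- vapply(kgrid, disc_at, 0)
  ks <- NA_real_; As <- NA_real_
  sign_change <- which(diff(sign(dvals)) != 0)
  for (sc in sign_change) {
    root <- stats::uniroot(disc_at, c(kgrid[sc], kgrid[sc + 1]),
                           tol = 1e-12)$root
    rpk <- rp; rpk$kappa <- root
    q <- interior_quadratic(rpk)
    A2 <- -q[["q2"]] / (2 * q[["q1"]])
    if (A2 > 0) { ks <- root; As <- A2; break }
  }
  structure(list(branches = do.call(rbind, branches),
                 kappa = kgrid, n_positive_interior = npos,
                 kappa_saddle_node = ks, A_saddle_node = As),
            class = "kappa_bifurcation")
}
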