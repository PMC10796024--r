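# Truncated-moment-equation landscape: per-attractor Gaussian stationary
# densities, weighted mixture, U = -ln p_ss, bipartite two-coordinate
# dimension reduction, reduced grids, saddles and barrier heights.

# Stationary covariance of the linearized Langevin dynamics around a stable
# fixed point with Jacobian A and isotropic diffusion d: the unique solution
# of the Lyapunov equation  A S + S A^T + 2 d I = 0, obtained exactly from
# the Kronecker-product linear system.
lyapunov_stationary <- function(A, d) {
  n <- nrow(A)
  I <- diag(n)
  M <- kronecker(I, A) + kronecker(A, I)
  S <- matrix(solve(M, -2 * d * as.vector(I)), n, n)
  (S + t(S)) / 2
}

#' Stationary Gaussian moments around an attractor
#'
#' Under the truncated moment-equation (second-order) closure of the
#' Fokker-Planck equation, the stationary density around a linearly stable
#' fixed point is Gaussian with mean at the fixed point and covariance
#' solving the Lyapunov equation `Sigma A^T + A Sigma + 2 d I = 0`, where
#' `A` is the drift Jacobian at the fixed point and `d` the noise intensity.
#'
#' @param state numeric fixed-point state (plants first, then pollinators).
#' @inheritParams glv_drift
#' @param d diffusion coefficient (noise intensity), `0 < d << 1`.
#' @return A list of class `gaussian_component` with `mean`, `cov`, `d` and
#'   the Lyapunov residual `resid`.
#' @export
stationary_moments <- function(state, net, params, d = 0.005,
                               gammas = NULL) {
  stopifnot(d > 0)
  sys <- glv_system(net, params, gammas)
  A <- sys$jac(state)
  if (spectral_abscissa(A) >= 0)
    stop("state is not linearly stable: no stationary covariance exists",
         call. = FALSE)
  S <- lyapunov_stationary(A, d)
  resid <- max(abs(S %*% t(A) + A %*% S + 2 * d * diag(nrow(A))))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10)
    stop("stationary covariance is not positive semi-definite",
         call. = FALSE)
  structure(list(mean = as.numeric(state), cov = S, d = d, resid = resid),
            class = "gaussian_component")
}

#' Assemble the Gaussian-mixture landscape
#'
#' The global stationary density of a multistable system is approximated by
#' the weighted sum of the per-attractor Gaussian stationary densities,
#' with basin-frequency weights `phi`. The potential energy landscape is
#' `U(x) = -ln p_ss(x)`.
#'
#' @param components list of [stationary_moments()] results (all with the
#'   same `d`).
#' @param weights basin weights `phi`, must sum to 1 within `1e-12`.
#' @param labels optional state labels (`high`/`intermediate`/`low`/...).
#' @return An object of class `gaussian_mixture` with fields `means` (one
#'   row per component), `covs`, `weights`, `labels`, `d`.
#' @export
assemble_mixture <- function(components, weights, labels = NULL) {
  stopifnot(length(components) >= 1,
            length(weights) == length(components))
  if (abs(sum(weights) - 1) > 1e-12)
    stop("mixture weights must sum to 1 (got ", sum(weights), ")",
         call. = FALSE)
  dd <- unique(vapply(components, function(cm) cm$d, 0))
  if (length(dd) != 1)
    stop("all components must share the same diffusion d", call. = FALSE)
  means <- do.call(rbind, lapply(components, function(cm) cm$mean))
  structure(list(means = means,
                 covs = lapply(components, function(cm) cm$cov),
                 weights = as.numeric(weights),
                 labels = labels %||% rep(NA_character_, length(components)),
                 d = dd),
            class = "gaussian_mixture")
}

#' Gaussian-mixture landscape from an attractor set
#'
#' Convenience wrapper: computes [stationary_moments()] for every attractor
#' of a [find_attractors()] result and assembles the weighted mixture with
#' the basin weights found there.
#'
#' @param attractors an `attractor_set` from [find_attractors()].
#' @inheritParams stationary_moments
#' @return A `gaussian_mixture` (see [assemble_mixture()]).
#' @export
tme_landscape <- function(attractors, d = 0.005, gammas = NULL) {
  stopifnot(inherits(attractors, "attractor_set"))
  comps <- lapply(seq_len(nrow(attractors$states)), function(i)
    stationary_moments(attractors$states[i, ], attractors$net,
                       attractors$params, d = d, gammas = gammas))
  assemble_mixture(comps, attractors$phi, labels = attractors$labels)
}

# Multivariate normal log-density via Cholesky.
dmvnorm_log <- function(x, mean, cov) {
  L <- chol(cov)
  r <- backsolve(L, x - mean, transpose = TRUE)
  -0.5 * sum(r^2) - sum(log(diag(L))) - 0.5 * length(x) * log(2 * pi)
}

#' Mixture stationary density and potential
#'
#' `mixture_density()` evaluates `p_ss(x)`; `mixture_potential()` evaluates
#' `U(x) = -ln p_ss(x)`. Both accept a vector or a matrix of row states.
#'
#' @param mix a `gaussian_mixture`.
#' @param x state vector, or matrix with one state per row.
#' @return Numeric vector of densities / potentials.
#' @export
mixture_density <- function(mix, x) {
  exp(-mixture_potential(mix, x))
}

#' @rdname mixture_density
#' @export
mixture_potential <- function(mix, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  apply(x, 1, function(xi) {
    lg <- vapply(seq_along(mix$weights), function(j)
      log(mix$weights[j]) + dmvnorm_log(xi, mix$means[j, ], mix$covs[[j]]),
      0)
    m <- max(lg)
    -(m + log(sum(exp(lg - m))))
  })
}

# Mixture marginal moments over a block of coordinates:
# mu = sum_j phi_j mu_j,  Sigma = sum_j phi_j (Sigma_j + mu_j mu_j^T) -
# mu mu^T (exact moment formula, not an approximation).
mixture_block_moments <- function(mix, idx) {
  mu <- colSums(mix$weights * mix$means[, idx, drop = FALSE])
  S <- Reduce(`+`, lapply(seq_along(mix$weights), function(j) {
    mj <- mix$means[j, idx]
    mix$weights[j] * (mix$covs[[j]][idx, idx, drop = FALSE] + outer(mj, mj))
  }))
  S <- S - outer(mu, mu)
  list(mean = mu, cov = (S + t(S)) / 2)
}

#' Bipartite two-coordinate projection (plant PC1 / pollinator PC1)
#'
#' Computes the marginal mixture covariance of the plant block and of the
#' pollinator block separately (exact mixture-moment formula) and takes the
#' leading eigenvector of each as projection weights: `z1 = w1_P' P`,
#' `z2 = w1_A' A`. Treating the two guilds separately gives both axes a
#' direct reading as aggregate plant and pollinator abundance. Signs are
#' fixed so that the component with the largest total abundance (the high
#' state) projects to the largest coordinate on both axes.
#'
#' @param mix a `gaussian_mixture`.
#' @param net the [bipartite_network()] the mixture was built on.
#' @return An object of class `bipartite_projection` with unit vectors
#'   `w1_P`, `w1_A` and the `(n_plants + n_pollinators) x 2` block matrix
#'   `W`.
#' @export
reduce_bipartite <- function(mix, net) {
  stopifnot(inherits(mix, "gaussian_mixture"),
            inherits(net, "bipartite_network"))
  np <- net$n_plants; na <- net$n_pollinators
  ip <- seq_len(np); ia <- np + seq_len(na)
  bp <- mixture_block_moments(mix, ip)
  ba <- mixture_block_moments(mix, ia)
  lead_vec <- function(S, block) {
    e <- eigen(S, symmetric = TRUE)
    if (e$values[1] <= 1e-14)
      stop("degenerate covariance in the ", block,
           " block: zero leading eigenvalue", call. = FALSE)
    e$vectors[, 1]
  }
  w1_P <- lead_vec(bp$cov, "plant")
  w1_A <- lead_vec(ba$cov, "pollinator")
  hi <- which.max(rowSums(mix$means))
  flip <- function(w, idx) {
    prj <- as.numeric(mix$means[, idx, drop = FALSE] %*% w)
    if (prj[hi] < mean(prj) || (length(prj) == 1 && sum(w) < 0)) -w else w
  }
  w1_P <- flip(w1_P, ip); w1_A <- flip(w1_A, ia)
  W <- matrix(0, np + na, 2)
  W[ip, 1] <- w1_P; W[ia, 2] <- w1_A
  structure(list(w1_P = w1_P, w1_A = w1_A, W = W, np = np, na = na),
            class = "bipartite_projection")
}

#' Project states onto the reduced coordinates
#'
#' @param proj a [reduce_bipartite()] projection.
#' @param x state vector or matrix of row states.
#' @return Matrix with columns `z1` (plant PC1 score) and `z2` (pollinator
#'   PC1 score).
#' @export
project_states <- function(proj, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  z <- x %*% proj$W
  colnames(z) <- c("z1", "z2")
  z
}

#' Reduced two-dimensional landscape on a grid
#'
#' Each mixture component projects to a bivariate Gaussian
#' `N(W' mu_j, W' Sigma_j W)`; the reduced potential is
#' `U(z1, z2) = -ln sum_j phi_j N(z; ...)` evaluated on a regular grid
#' spanning the projected means plus a margin of projected standard
#' deviations.
#'
#' @param mix a `gaussian_mixture`.
#' @param proj a [reduce_bipartite()] projection (possibly computed at a
#'   reference parameter set, so that landscapes across a sweep share
#'   coordinates).
#' @param n_grid grid points per axis (default 200).
#' @param margin margin in projected standard deviations (default 4).
#' @param z1_range,z2_range optional explicit axis ranges.
#' @param ceiling display ceiling for `U` stored in `U_capped`; the raw
#'   values are kept in `U`.
#' @return An object of class `reduced_landscape`: grids `z1`, `z2`, matrix
#'   `U` (`n_grid x n_grid`, rows index `z1`), projected component means
#'   `means_z`, covariances `covs_z`, `weights`, `labels`, and per-basin
#'   minimum cells `minima`.
#' @export
reduced_landscape <- function(mix, proj, n_grid = 200, margin = 4,
                              z1_range = NULL, z2_range = NULL,
                              ceiling = NULL) {
  M <- length(mix$weights)
  means_z <- t(vapply(seq_len(M), function(j)
    as.numeric(t(proj$W) %*% mix$means[j, ]), numeric(2)))
  covs_z <- lapply(seq_len(M), function(j) {
    C <- t(proj$W) %*% mix$covs[[j]] %*% proj$W
    (C + t(C)) / 2
  })
  sds <- t(vapply(covs_z, function(C) sqrt(pmax(diag(C), 0)), numeric(2)))
  z1_range <- z1_range %||% range(means_z[, 1] + margin * sds[, 1],
                                  means_z[, 1] - margin * sds[, 1])
  z2_range <- z2_range %||% range(means_z[, 2] + margin * sds[, 2],
                                  means_z[, 2] - margin * sds[, 2])
  z1 <- seq(z1_range[1], z1_range[2], length.out = n_grid)
  z2 <- seq(z2_range[1], z2_range[2], length.out = n_grid)
  # log-density of each component on the grid, combined by log-sum-exp
  lg <- array(-Inf, c(n_grid, n_grid, M))
  for (j in seq_len(M)) {
    C <- covs_z[[j]]
    Ci <- solve(C)
    ldet <- determinant(C, logarithm = TRUE)$modulus
    dz1 <- z1 - means_z[j, 1]
    dz2 <- z2 - means_z[j, 2]
    q <- outer(dz1^2, rep(Ci[1, 1], n_grid)) +
      2 * Ci[1, 2] * outer(dz1, dz2) +
      outer(rep(Ci[2, 2], n_grid), dz2^2)
    lg[, , j] <- log(mix$weights[j]) - 0.5 * q - 0.5 * ldet - log(2 * pi)
  }
  mx <- apply(lg, c(1, 2), max)
  U <- -(mx + log(apply(exp(lg - as.vector(mx)), c(1, 2), sum)))
  minima <- t(vapply(seq_len(M), function(j) {
    ci <- c(which.min(abs(z1 - means_z[j, 1])),
            which.min(abs(z2 - means_z[j, 2])))
    descend_grid(U, ci)
  }, numeric(2)))
  out <- structure(list(z1 = z1, z2 = z2, U = U, means_z = means_z,
                        covs_z = covs_z, weights = mix$weights,
                        labels = mix$labels, minima = minima, d = mix$d),
                   class = "reduced_landscape")
  if (!is.null(ceiling)) out$U_capped <- pmin(U, ceiling)
  out
}

# Steepest-descent walk on the grid from cell ci to the local minimum.
descend_grid <- function(U, ci) {
  n1 <- nrow(U); n2 <- ncol(U)
  repeat {
    i <- ci[1]; j <- ci[2]
    nb <- rbind(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1),
                c(i - 1, j - 1), c(i - 1, j + 1), c(i + 1, j - 1),
                c(i + 1, j + 1))
    nb <- nb[nb[, 1] >= 1 & nb[, 1] <= n1 & nb[, 2] >= 1 & nb[, 2] <= n2, ,
             drop = FALSE]
    vals <- U[nb]
    if (all(vals >= U[i, j])) return(c(i, j))
    ci <- nb[which.min(vals), ]
  }
}

#' Saddle point between two basins of a reduced landscape
#'
#' Finds the lowest crossing level between two basins: the smallest level
#' `c` such that the two basin minima lie in one 4-connected component of
#' the sublevel set `{U <= c}`. Cells are merged in increasing order of `U`
#' with a union-find structure, which yields the exact grid minimax level;
#' the cell whose insertion first connects the basins is the saddle.
#'
#' @param reduced a [reduced_landscape()].
#' @param basin_i,basin_j component indices (into the mixture) or state
#'   labels (`"high"`, `"intermediate"`, `"low"`).
#' @return A list with `z_saddle`, `U_saddle`, `U_i`, `U_j` (basin minimum
#'   potentials), and `merged = TRUE` with zero barrier if the two labels
#'   fall into a single basin on the grid.
#' @export
find_saddle <- function(reduced, basin_i, basin_j) {
  bi <- resolve_basin(reduced, basin_i)
  bj <- resolve_basin(reduced, basin_j)
  U <- reduced$U
  n1 <- nrow(U); n2 <- ncol(U)
  ci <- reduced$minima[bi, ]; cj <- reduced$minima[bj, ]
  id_i <- (ci[2] - 1) * n1 + ci[1]
  id_j <- (cj[2] - 1) * n1 + cj[1]
  U_i <- U[ci[1], ci[2]]; U_j <- U[cj[1], cj[2]]
  if (id_i == id_j)
    return(list(z_saddle = c(reduced$z1[ci[1]], reduced$z2[ci[2]]),
                U_saddle = U_i, U_i = U_i, U_j = U_j, merged = TRUE))
  ord <- order(as.vector(U))
  parent <- seq_len(n1 * n2)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  active <- logical(n1 * n2)
  for (cell in ord) {
    active[cell] <- TRUE
    i <- ((cell - 1) %% n1) + 1
    j <- ((cell - 1) %/% n1) + 1
    for (nb in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
      if (nb[1] < 1 || nb[1] > n1 || nb[2] < 1 || nb[2] > n2) next
      nc <- (nb[2] - 1) * n1 + nb[1]
      if (active[nc]) {
        ra <- find(cell); rb <- find(nc)
        if (ra != rb) parent[ra] <- rb
      }
    }
    if (find(id_i) == find(id_j)) {
      return(list(z_saddle = c(reduced$z1[i], reduced$z2[j]),
                  U_saddle = U[i, j], U_i = U_i, U_j = U_j,
                  merged = FALSE))
    }
  }
  stop("basins never connect on the grid", call. = FALSE)
}

resolve_basin <- function(reduced, b) {
  if (is.character(b)) {
    k <- which(reduced$labels == b)
    if (length(k) != 1)
      stop("basin label '", b, "' does not identify exactly one component",
           call. = FALSE)
    return(k)
  }
  stopifnot(b >= 1, b <= nrow(reduced$means_z))
  as.integer(b)
}

#' Barrier heights and relative barrier heights
#'
#' For each requested pair of basins, reports the barrier height
#' `BH_si = U_saddle - U_i` seen from each side and the relative barrier
#' height `RBH_ij = BH_sj - BH_si`, whose sign indicates the easier
#' transition direction (positive means leaving `i` costs less than
#' leaving `j`... i.e. basin `j` is the deeper one). Antisymmetry
#' `RBH_ij = -RBH_ji` holds by construction.
#'
#' @param reduced a [reduced_landscape()].
#' @param pairs optional 2-column matrix (or list of length-2 vectors) of
#'   basin indices/labels; default all unordered pairs.
#' @return A data frame of class `barrier_report` with one row per pair:
#'   `i`, `j`, `U_saddle`, `BH_i`, `BH_j`, `RBH_ij`, `merged`.
#' @export
barrier_report <- function(reduced, pairs = NULL) {
  M <- nrow(reduced$means_z)
  if (M < 2) stop("barrier report needs at least two basins", call. = FALSE)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(M, 2))
  } else if (is.list(pairs)) {
    pairs <- do.call(rbind, pairs)
  }
  rows <- lapply(seq_len(nrow(pairs)), function(r) {
    s <- find_saddle(reduced, pairs[r, 1], pairs[r, 2])
    bi <- resolve_basin(reduced, pairs[r, 1])
    bj <- resolve_basin(reduced, pairs[r, 2])
    data.frame(i = lab_or_idx(reduced, bi), j = lab_or_idx(reduced, bj),
               U_saddle = s$U_saddle,
               BH_i = s$U_saddle - s$U_i, BH_j = s$U_saddle - s$U_j,
               RBH_ij = (s$U_saddle - s$U_j) - (s$U_saddle - s$U_i),
               merged = s$merged)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("barrier_report", class(out))
  out
}

lab_or_idx <- function(reduced, k) {
  if (!is.na(reduced$labels[k])) reduced$labels[k] else as.character(k)
}

#' Export a reduced landscape as a delimited grid table
#'
#' Writes rows `(z1, z2, U)` as comma-separated text; with
#' `format = "rds"` the full object is serialized instead (a binary array
#' container for downstream tooling).
#'
#' @param reduced a [reduced_landscape()].
#' @param path output path.
#' @param format `"table"` (default) or `"rds"`.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(reduced, path, format = c("table", "rds")) {
  format <- match.arg(format)
  if (format == "rds") {
    saveRDS(reduced, path)
    return(invisible(path))
  }
  g <- expand.grid(z1 = reduced$z1, z2 = reduced$z2)
  g$U <- as.vector(reduced$U)
  utils::write.csv(g, path, row.names = FALSE)
  invisible(path)
}
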