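# Freidlin-Wentzell transition actions and minimum-action paths.
#
# The machinery works on a generic drift/Jacobian pair so that the same
# optimizer serves the full network model and low-dimensional test systems;
# transition_path() wraps it for bipartite networks.

#' Discretized Freidlin-Wentzell action of a path
#'
#' The action of a path `x(t)`, `t in [0, T]`, is
#' `S = 1/2 * integral ||dx/dt - f(x)||^2 dt`. It vanishes iff the path
#' follows the deterministic flow, and its minimum over paths between two
#' attractors sets the exponential cost of the noise-induced transition.
#' The discretization uses segment finite differences for `dx/dt` and the
#' drift at segment midpoints (midpoint quadrature).
#'
#' @param nodes `L x N` matrix of path nodes (rows are states).
#' @param times length-`L` increasing time grid.
#' @param f drift function `f(x) -> dx/dt`.
#' @return Non-negative scalar action.
#' @export
path_action <- function(nodes, times, f) {
  L <- nrow(nodes)
  stopifnot(L >= 2, length(times) == L)
  dt <- diff(times)
  if (any(dt <= 0)) stop("times must be strictly increasing", call. = FALSE)
  S <- 0
  for (k in seq_len(L - 1)) {
    xdot <- (nodes[k + 1, ] - nodes[k, ]) / dt[k]
    fm <- f((nodes[k, ] + nodes[k + 1, ]) / 2)
    S <- S + 0.5 * sum((xdot - fm)^2) * dt[k]
  }
  S
}

# Action and its analytic gradient w.r.t. the interior nodes (endpoints
# fixed). Gradient of segment k touches nodes k and k+1:
#   dS/dx_k   = dt_k * r_k^T (-I/dt_k - J(m_k)/2)
#   dS/dx_k+1 = dt_k * r_k^T ( I/dt_k - J(m_k)/2)
# with r_k = xdot_k - f(m_k) and m_k the segment midpoint.
action_with_grad <- function(nodes, times, f, jac) {
  L <- nrow(nodes); N <- ncol(nodes)
  dt <- diff(times)
  G <- matrix(0, L, N)
  S <- 0
  for (k in seq_len(L - 1)) {
    m <- (nodes[k, ] + nodes[k + 1, ]) / 2
    r <- (nodes[k + 1, ] - nodes[k, ]) / dt[k] - f(m)
    S <- S + 0.5 * sum(r^2) * dt[k]
    Jr <- as.numeric(crossprod(jac(m), r))   # J(m)^T r
    G[k, ] <- G[k, ] - r - 0.5 * dt[k] * Jr
    G[k + 1, ] <- G[k + 1, ] + r - 0.5 * dt[k] * Jr
  }
  list(S = S, grad = G)
}

# Equidistribute L nodes along the arc length of a path (linear
# interpolation in the path's own parameter), keeping the endpoints.
# Returns new nodes and the (rescaled) times assigned to them.
remesh_arclength <- function(nodes, times) {
  L <- nrow(nodes)
  seglen <- sqrt(rowSums((nodes[-1, , drop = FALSE] -
                            nodes[-L, , drop = FALSE])^2))
  if (sum(seglen) < 1e-12) return(list(nodes = nodes, times = times))
  s <- c(0, cumsum(seglen))
  targets <- seq(0, s[L], length.out = L)
  new_nodes <- matrix(0, L, ncol(nodes))
  new_times <- numeric(L)
  for (i in seq_len(L)) {
    k <- findInterval(targets[i], s, rightmost.closed = TRUE)
    k <- min(max(k, 1), L - 1)
    w <- if (s[k + 1] > s[k]) (targets[i] - s[k]) / (s[k + 1] - s[k]) else 0
    new_nodes[i, ] <- (1 - w) * nodes[k, ] + w * nodes[k + 1, ]
    new_times[i] <- (1 - w) * times[k] + w * times[k + 1]
  }
  new_nodes[1, ] <- nodes[1, ]; new_nodes[L, ] <- nodes[L, ]
  new_times <- sort(new_times)
  new_times[1] <- times[1]; new_times[L] <- times[L]
  # guard against coincident times
  for (i in 2:L) if (new_times[i] <= new_times[i - 1])
    new_times[i] <- new_times[i - 1] + (times[L] - times[1]) * 1e-6
  list(nodes = new_nodes, times = new_times)
}

#' Minimum-action path between two states
#'
#' Minimizes the discretized Freidlin-Wentzell action over the interior
#' nodes of an `L`-node path with fixed endpoints, subject to the physical
#' constraint that all abundances stay non-negative (bound-constrained
#' L-BFGS-B with the analytic action gradient). For each horizon `T` in
#' `T_schedule` the path is optimized on a uniform time mesh and then
#' re-optimized after arc-length remeshing (nodes concentrated where the
#' path moves fast); the best result over the schedule is returned, since
#' the uphill action is approached from above as `T` grows while very large
#' `T` degrades the conditioning of the discretization.
#'
#' @param x_from,x_to endpoint states (typically attractors).
#' @param f,jac drift and Jacobian functions.
#' @param L number of path nodes (default 20).
#' @param T_schedule candidate total transition times.
#' @param init optional `L x N` matrix of initial nodes; default straight
#'   line.
#' @param n_remesh arc-length remesh/re-optimize rounds per horizon.
#' @param maxit L-BFGS-B iteration cap per optimization round.
#' @param lower lower node bound (0 for abundances; `-Inf` disables).
#' @return An object of class `transition_path`: `nodes`, `times`, `action`,
#'   `T`, `converged`, `final_gradient_norm`.
#' @export
minimize_action <- function(x_from, x_to, f, jac, L = 20,
                            T_schedule = c(20, 50, 100, 200),
                            init = NULL, n_remesh = 2, maxit = 400,
                            lower = 0) {
  N <- length(x_from)
  stopifnot(length(x_to) == N, L >= 3)
  if (max(abs(x_from - x_to)) < 1e-12) {
    nodes <- matrix(rep(x_from, each = L), L, N)
    return(structure(list(nodes = nodes, times = seq(0, 1, length.out = L),
                          action = 0, T = 1, converged = TRUE,
                          final_gradient_norm = 0),
                     class = "transition_path"))
  }
  base_init <- init %||% outer(seq(0, 1, length.out = L), x_to - x_from) +
    matrix(rep(x_from, each = L), L, N)
  best <- NULL
  for (Ttot in T_schedule) {
    nodes <- base_init
    times <- seq(0, Ttot, length.out = L)
    res <- optimize_path(nodes, times, f, jac, maxit, lower)
    res$S_ref <- refined_action(res$nodes, res$times, f)
    for (r in seq_len(n_remesh)) {
      rm <- remesh_arclength(res$nodes, res$times)
      res2 <- optimize_path(rm$nodes, rm$times, f, jac, maxit, lower)
      res2$S_ref <- refined_action(res2$nodes, res2$times, f)
      if (res2$S_ref < res$S_ref) res <- res2
    }
    if (is.null(best) || res$S_ref < best$S_ref)
      best <- c(res, list(T = Ttot))
  }
  structure(list(nodes = best$nodes, times = best$times,
                 action = best$S_ref, action_coarse = best$S,
                 T = best$T, converged = best$converged,
                 final_gradient_norm = best$gnorm),
            class = "transition_path")
}

# Action of the piecewise-linear path evaluated on a k-fold refined time
# grid. An under-resolved optimum (too few nodes for the chosen horizon)
# reveals itself by a refined action much larger than the coarse one, so
# horizon selection and reporting use this value.
refined_action <- function(nodes, times, f, k = 4) {
  L <- nrow(nodes)
  tt <- numeric((L - 1) * k + 1)
  nd <- matrix(0, (L - 1) * k + 1, ncol(nodes))
  r <- 1L
  for (s in seq_len(L - 1)) {
    for (q in seq_len(k)) {
      w <- (q - 1) / k
      tt[r] <- (1 - w) * times[s] + w * times[s + 1]
      nd[r, ] <- (1 - w) * nodes[s, ] + w * nodes[s + 1, ]
      r <- r + 1L
    }
  }
  tt[r] <- times[L]; nd[r, ] <- nodes[L, ]
  path_action(nd, tt, f)
}

optimize_path <- function(nodes, times, f, jac, maxit, lower) {
  L <- nrow(nodes); N <- ncol(nodes)
  interior <- 2:(L - 1)
  pack <- function(nd) as.vector(nd[interior, , drop = FALSE])
  unpack <- function(par) {
    nd <- nodes
    nd[interior, ] <- matrix(par, length(interior), N)
    nd
  }
  obj <- function(par) path_action(unpack(par), times, f)
  grd <- function(par) {
    ag <- action_with_grad(unpack(par), times, f, jac)
    as.vector(ag$grad[interior, , drop = FALSE])
  }
  opt <- stats::optim(pack(nodes), obj, grd, method = "L-BFGS-B",
                      lower = lower,
                      control = list(maxit = maxit, factr = 1e4))
  nd <- unpack(opt$par)
  ag <- action_with_grad(nd, times, f, jac)
  list(nodes = nd, times = times, S = opt$value,
       converged = opt$convergence == 0,
       gnorm = max(abs(ag$grad[interior, , drop = FALSE])))
}

#' @export
print.transition_path <- function(x, ...) {
  cat(sprintf("transition_path: %d nodes, T=%g, action S=%.6g%s\n",
              nrow(x$nodes), x$T, x$action,
              if (isTRUE(x$converged)) "" else " (optimizer not converged)"))
  invisible(x)
}

# Wrap a network system into (f, jac) closures at fixed parameters.
system_funs <- function(net, params, gammas = NULL) {
  sys <- glv_system(net, params, gammas)
  list(f = function(x) sys$f(x), jac = function(x) sys$jac(x))
}

#' Minimum-action transition path in a mutualistic network
#'
#' @inheritParams glv_drift
#' @param x_from,x_to attractor states (plants first).
#' @param ... passed to [minimize_action()].
#' @return A `transition_path`.
#' @export
transition_path <- function(net, params, x_from, x_to, gammas = NULL, ...) {
  fs <- system_funs(net, params, gammas)
  minimize_action(x_from, x_to, fs$f, fs$jac, ...)
}

#' Indirect path through an intermediate attractor
#'
#' Concatenates the minimum-action paths `x_from -> x_mid` and
#' `x_mid -> x_to` and resamples the concatenation to `L` nodes by arc
#' length. Because the indirect route optimizes over a restricted set of
#' paths (those visiting the waypoint), its action is never below the
#' direct optimum.
#'
#' @inheritParams transition_path
#' @param x_mid waypoint attractor state (e.g. the intermediate state).
#' @param L nodes in the returned concatenated path (default 20).
#' @param ... passed to [minimize_action()] for both legs.
#' @return A `transition_path` whose `action` is the sum of the two legs.
#' @export
indirect_path <- function(net, params, x_from, x_mid, x_to, L = 20,
                          gammas = NULL, ...) {
  if (is.null(x_mid)) stop("intermediate state required", call. = FALSE)
  fs <- system_funs(net, params, gammas)
  p1 <- minimize_action(x_from, x_mid, fs$f, fs$jac, L = L, ...)
  p2 <- minimize_action(x_mid, x_to, fs$f, fs$jac, L = L, ...)
  nodes <- rbind(p1$nodes, p2$nodes[-1, , drop = FALSE])
  times <- c(p1$times, p1$times[length(p1$times)] + p2$times[-1])
  rs <- remesh_arclength(nodes, times)
  idx <- round(seq(1, nrow(rs$nodes), length.out = L))
  structure(list(nodes = rs$nodes[idx, , drop = FALSE],
                 times = rs$times[idx], action = p1$action + p2$action,
                 T = p1$T + p2$T,
                 converged = p1$converged && p2$converged,
                 final_gradient_norm = max(p1$final_gradient_norm,
                                           p2$final_gradient_norm),
                 legs = list(p1, p2)),
            class = "transition_path")
}

# Resample a path to exactly L nodes by arc length.
resample_path <- function(path, L) {
  if (nrow(path$nodes) == L) return(path)
  rm <- remesh_arclength(path$nodes, path$times)
  idx <- round(seq(1, nrow(rm$nodes), length.out = L))
  path$nodes <- rm$nodes[idx, , drop = FALSE]
  path$times <- rm$times[idx]
  path
}

#' Path distance between a direct and an indirect path
#'
#' `PD = sum_i || y_i(direct) - y_i(indirect) ||_2^2` over the `L` path
#' nodes in the full abundance space. Paths with differing node counts are
#' resampled to `L` by arc length first.
#'
#' @param p_direct,p_indirect `transition_path` objects.
#' @param L common node count (default 20).
#' @return Non-negative scalar.
#' @export
path_distance <- function(p_direct, p_indirect, L = 20) {
  p1 <- resample_path(p_direct, L)
  p2 <- resample_path(p_indirect, L)
  sum((p1$nodes - p2$nodes)^2)
}

#' Forward/backward action asymmetry
#'
#' `Delta S = S(i -> j) - S(j -> i)`; a negative value means the forward
#' transition `i -> j` is the easier direction. Like the relative barrier
#' height, the sign tracks which basin is the more stable one.
#'
#' @inheritParams transition_path
#' @param x_i,x_j the two attractor states.
#' @param ... passed to [minimize_action()].
#' @return A list with `delta_S`, `S_forward`, `S_backward` and the two
#'   paths.
#' @export
action_asymmetry <- function(net, params, x_i, x_j, gammas = NULL, ...) {
  fs <- system_funs(net, params, gammas)
  pf <- minimize_action(x_i, x_j, fs$f, fs$jac, ...)
  pb <- minimize_action(x_j, x_i, fs$f, fs$jac, ...)
  list(delta_S = pf$action - pb$action, S_forward = pf$action,
       S_backward = pb$action, forward = pf, backward = pb)
}

#' Per-species min-max normalization of a path
#'
#' Linearly rescales each species' abundance along the path to `[0, 1]`
#' (its own minimum maps to 0 and maximum to 1), the form used for
#' multi-species transition heatmaps. A species that is constant along the
#' path maps to all zeros.
#'
#' @param path a `transition_path` (or a plain node matrix).
#' @return `L x N` matrix with values in `[0, 1]`.
#' @export
normalize_path_heatmap <- function(path) {
  nodes <- if (inherits(path, "transition_path")) path$nodes else path
  apply(nodes, 2, function(v) {
    rng <- range(v)
    if (diff(rng) < .Machine$double.eps * max(1, abs(rng[2])))
      rep(0, length(v))
    else (v - rng[1]) / diff(rng)
  })
}

#' Export a transition path as a delimited table
#'
#' @param path a `transition_path`.
#' @param net optional [bipartite_network()] supplying species column names.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_path <- function(path, file, net = NULL) {
  df <- data.frame(node = seq_len(nrow(path$nodes)), time = path$times)
  nodes <- path$nodes
  colnames(nodes) <- if (!is.null(net))
    c(net$plant_labels, net$pollinator_labels)
  else paste0("x", seq_len(ncol(nodes)))
  utils::write.csv(cbind(df, nodes), file, row.names = FALSE)
  invisible(file)
}
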