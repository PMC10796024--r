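# Langevin simulation (Euler-Maruyama), white and colored noise, mean
# first passage times, ramped-kappa collapse/recovery and hysteresis
# thresholds. The network stepper is compiled; a pure-R stepper serves
# arbitrary low-dimensional drifts in tests and oracles.

#' Noise specification
#'
#' White noise has independent Gaussian increments with
#' `<zeta_i(t) zeta_j(t')> = 2 d delta_ij delta(t - t')`. Colored noise is
#' generated as per-species AR(1) innovation streams with lag-1
#' autocorrelation `rho` (positive: red, negative: blue),
#' variance-normalized so the stationary innovation variance matches the
#' white case at the same intensity `d`.
#'
#' @param d diffusion coefficient (noise intensity), `>= 0`.
#' @param kind `"white"`, `"red"` or `"blue"`.
#' @param rho lag-1 autocorrelation for colored kinds; defaults `+0.5`
#'   (red) / `-0.5` (blue); must be 0 for white.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(d, kind = c("white", "red", "blue"), rho = NULL) {
  kind <- match.arg(kind)
  stopifnot(d >= 0)
  rho <- rho %||% switch(kind, white = 0, red = 0.5, blue = -0.5)
  if (kind == "white" && rho != 0)
    stop("white noise requires rho = 0", call. = FALSE)
  if (kind == "red" && rho <= 0) stop("red noise requires rho > 0",
                                      call. = FALSE)
  if (kind == "blue" && rho >= 0) stop("blue noise requires rho < 0",
                                       call. = FALSE)
  if (abs(rho) >= 1) stop("rho must lie in (-1, 1)", call. = FALSE)
  structure(list(d = d, kind = kind, rho = rho), class = "noise_spec")
}

#' Euler-Maruyama simulation of the network Langevin equation
#'
#' Steps `x_{k+1} = x_k + f(x_k) dt + sqrt(2 d dt) eta_k` with per-species
#' noise streams (see [noise_spec()]), clipping abundances at zero after
#' every step (reflecting boundary by truncation). With `d = 0` the scheme
#' reduces to deterministic Euler.
#'
#' @inheritParams glv_drift
#' @param x0 initial state.
#' @param noise a [noise_spec()].
#' @param dt time step.
#' @param t_end final time.
#' @param seed integer seed (`NULL` uses the session RNG).
#' @param record_every record every k-th step (thinning; default 10).
#' @param kappa_schedule optional vector of per-step additive shifts to
#'   `kappa` (length `n_steps`), used by parameter ramps.
#' @return A list of class `langevin_trajectory` with `times`, `states`
#'   (one recorded row per time), `x_final`, `dt`, `noise`.
#' @export
simulate_langevin <- function(net, params, x0, noise, dt = 0.01,
                              t_end = 100, seed = NULL, record_every = 10,
                              kappa_schedule = NULL, gammas = NULL) {
  stopifnot(inherits(noise, "noise_spec"), dt > 0, all(x0 >= 0))
  sys <- glv_system(net, params, gammas)
  n_steps <- ceiling(t_end / dt)
  ks <- kappa_schedule %||% 0
  if (length(ks) > 1 && length(ks) != n_steps)
    stop("kappa_schedule must have one entry per step", call. = FALSE)
  out <- with_seed(seed,
    glv_em_cpp(as.numeric(x0), sys$rp, sys$gammas$gamma_PA,
               sys$gammas$gamma_AP, dt, n_steps, record_every,
               noise$d, noise$rho, as.numeric(ks)))
  structure(list(times = out$times, states = out$states,
                 x_final = out$x_final, dt = dt, noise = noise),
            class = "langevin_trajectory")
}

#' Generic Euler-Maruyama stepper for arbitrary drifts
#'
#' Pure-R reference stepper used for low-dimensional oracle systems; same
#' scheme as [simulate_langevin()] but with an arbitrary drift function and
#' optional clipping.
#'
#' @param x0 initial state.
#' @param f drift function.
#' @param noise a [noise_spec()].
#' @param dt,t_end step size and final time.
#' @param seed integer seed.
#' @param clip clip states at 0 after each step (default `FALSE` for
#'   abstract systems).
#' @param record_every thinning interval.
#' @return A list with `times` and `states`.
#' @export
euler_maruyama <- function(x0, f, noise, dt = 0.01, t_end = 100,
                           seed = NULL, clip = FALSE, record_every = 1) {
  stopifnot(inherits(noise, "noise_spec"), dt > 0)
  n_steps <- ceiling(t_end / dt)
  N <- length(x0)
  amp <- sqrt(2 * noise$d * dt)
  rho <- noise$rho
  with_seed(seed, {
    n_rec <- n_steps %/% record_every + 1
    states <- matrix(NA_real_, n_rec, N)
    times <- numeric(n_rec)
    x <- x0
    eta <- if (noise$d > 0) stats::rnorm(N) else numeric(N)
    states[1, ] <- x; ri <- 2L
    for (s in seq_len(n_steps)) {
      x <- x + f(x) * dt + amp * eta
      if (clip) x <- pmax(x, 0)
      if (any(!is.finite(x))) stop("non-finite state at step ", s,
                                   call. = FALSE)
      if (noise$d > 0) {
        eta <- if (rho != 0) rho * eta + sqrt(1 - rho^2) * stats::rnorm(N)
               else stats::rnorm(N)
      }
      if (s %% record_every == 0 && ri <= n_rec) {
        states[ri, ] <- x; times[ri] <- s * dt; ri <- ri + 1L
      }
    }
    list(times = times[seq_len(ri - 1)],
         states = states[seq_len(ri - 1), , drop = FALSE])
  })
}

#' Mean first passage time between attractors
#'
#' Repeated Langevin runs started at `x_from`; the first passage is the
#' first entry into a ball around `x_to`, measured in the reduced
#' plant/pollinator coordinates when a projection is supplied (the default
#' recommendation) and in the full state space otherwise. The ball radius
#' defaults to 25% of the inter-attractor distance in the coordinates
#' used. Runs that do not arrive by `t_max` are censored and reported
#' separately, never averaged in.
#'
#' @inheritParams simulate_langevin
#' @param x_from,x_to attractor states.
#' @param n_reps number of replicate runs.
#' @param t_max censoring horizon per run.
#' @param proj optional [reduce_bipartite()] projection.
#' @param radius arrival ball radius; default 25% of the inter-attractor
#'   distance.
#' @param seed master seed; replicate `r` uses a derived seed.
#' @return A list with `mfpt`, `se`, `times` (uncensored first passage
#'   times), `n_censored`, `radius`.
#' @export
mfpt <- function(net, params, x_from, x_to, noise, n_reps = 20,
                 dt = 0.01, t_max = 5000, proj = NULL, radius = NULL,
                 seed = 1, gammas = NULL) {
  stopifnot(n_reps >= 1)
  sys <- glv_system(net, params, gammas)
  W <- if (!is.null(proj)) proj$W else diag(sys$n)
  z_to <- as.numeric(t(W) %*% x_to)
  z_from <- as.numeric(t(W) %*% x_from)
  radius <- radius %||% (0.25 * sqrt(sum((z_to - z_from)^2)))
  n_steps <- ceiling(t_max / dt)
  times <- vapply(seq_len(n_reps), function(r)
    with_seed(child_seed(seed, r),
      glv_fpt_cpp(as.numeric(x_from), sys$rp, sys$gammas$gamma_PA,
                  sys$gammas$gamma_AP, dt, n_steps, noise$d, noise$rho,
                  W, z_to, radius)),
    0)
  ok <- times > 0
  if (!any(ok))
    return(list(mfpt = NA_real_, se = NA_real_, times = numeric(0),
                n_censored = n_reps, radius = radius))
  list(mfpt = mean(times[ok]),
       se = stats::sd(times[ok]) / sqrt(sum(ok)),
       times = times[ok], n_censored = sum(!ok), radius = radius)
}

#' Ramp specification for collapse / recovery simulations
#'
#' @param from,to start and end values of the ramped decay rate `kappa`.
#' @param rate absolute change of `kappa` per unit time.
#' @param fluctuation_sd optional standard deviation of weakly
#'   autocorrelated fluctuations added to the ramp (an AR(1) stream with
#'   lag-1 autocorrelation `fluctuation_rho`); used by the false-positive
#'   protocol with `rate = 0`.
#' @param fluctuation_rho lag-1 autocorrelation of the `kappa` fluctuations
#'   (default 0.2).
#' @return An object of class `ramp_spec`. `direction` is `"collapse"` for
#'   increasing and `"recovery"` for decreasing ramps.
#' @export
ramp_spec <- function(from, to, rate, fluctuation_sd = 0,
                      fluctuation_rho = 0.2) {
  stopifnot(rate >= 0, fluctuation_sd >= 0)
  if (rate == 0 && fluctuation_sd == 0)
    stop("either a nonzero rate or kappa fluctuations are required",
         call. = FALSE)
  structure(list(from = from, to = to, rate = rate,
                 fluctuation_sd = fluctuation_sd,
                 fluctuation_rho = fluctuation_rho,
                 direction = if (to >= from) "collapse" else "recovery"),
            class = "ramp_spec")
}

#' Ramped-kappa Langevin simulation with state labelling
#'
#' Simulates the Langevin dynamics while the pollinator decay rate `kappa`
#' changes linearly in time (optionally with weak AR(1) fluctuations), and
#' labels every recorded point with the nearest frozen-parameter attractor
#' in the reduced coordinates. Transition times are the first sustained
#' residence changes (dwell at least `dwell` time units in the new state);
#' the `kappa` value at each such change is the empirical
#' collapse/recovery threshold.
#'
#' @inheritParams simulate_langevin
#' @param spec a [ramp_spec()].
#' @param proj a [reduce_bipartite()] projection used both for labelling
#'   and for attractor matching; computed at `spec$from` when `NULL`.
#' @param kappa_step grid spacing of the frozen-parameter attractor
#'   continuation used for labelling (default 0.01).
#' @param dwell sustained-residence time (default 50).
#' @param n_starts,x_hi settings of the base attractor search.
#' @param base optional precomputed `attractor_set` at `spec$from`.
#' @param continuation optional precomputed [continue_attractors()] result
#'   covering the ramp range (shared across an ensemble of ramps).
#' @return A list of class `ramp_result`: `times`, `kappa`, `states`
#'   (thinned), `labels`, `transitions` (data frame `time`, `kappa`,
#'   `from`, `to`), `spec`.
#' @export
ramp_simulation <- function(net, params, spec, noise, x0 = NULL,
                            dt = 0.01, seed = 1, record_every = 25,
                            proj = NULL, kappa_step = 0.01, dwell = 50,
                            n_starts = 30, x_hi = NULL, base = NULL,
                            continuation = NULL, gammas = NULL) {
  stopifnot(inherits(spec, "ramp_spec"))
  p0 <- update_params(params, kappa = spec$from)
  base <- base %||% find_attractors(net, p0, n_starts = n_starts,
                                    seed = seed, x_hi = x_hi)
  if (is.null(proj)) {
    mix0 <- tme_landscape(base, d = noise$d)
    proj <- reduce_bipartite(mix0, net)
  }
  if (is.null(x0)) {
    start_lab <- if (spec$direction == "collapse") "high" else "low"
    k <- which(base$labels == start_lab)
    if (!length(k)) k <- which.max(base$phi)
    x0 <- base$states[k[1], ]
  }
  t_end <- if (spec$rate > 0) abs(spec$to - spec$from) / spec$rate else 500
  n_steps <- ceiling(t_end / dt)
  drift_k <- (if (spec$rate > 0)
    seq(spec$from, spec$to, length.out = n_steps) else
      rep(spec$from, n_steps)) - params$kappa[1]
  if (spec$fluctuation_sd > 0) {
    fl <- with_seed(child_seed(seed, 777), {
      e <- stats::rnorm(n_steps)
      stats::filter(e * sqrt(1 - spec$fluctuation_rho^2) *
                      spec$fluctuation_sd,
                    spec$fluctuation_rho, method = "recursive")
    })
    drift_k <- drift_k + as.numeric(fl)
  }
  tr <- simulate_langevin(net, params, x0, noise, dt = dt, t_end = t_end,
                          seed = seed, record_every = record_every,
                          kappa_schedule = drift_k, gammas = gammas)
  kappa_t <- params$kappa[1] +
    drift_k[pmin(pmax(round(tr$times / dt), 1), n_steps)]
  # frozen-parameter attractor continuation for labelling
  cont <- continuation %||% {
    kgrid <- seq(min(spec$from, spec$to), max(spec$from, spec$to),
                 by = kappa_step)
    continue_attractors(net, params, kgrid, base = base)
  }
  labels <- label_trajectory(tr$states, kappa_t, cont, proj)
  transitions <- residence_transitions(tr$times, kappa_t, labels, dwell)
  structure(list(times = tr$times, kappa = kappa_t, states = tr$states,
                 labels = labels, transitions = transitions, spec = spec,
                 proj = proj),
            class = "ramp_result")
}

# Nearest-attractor labelling in reduced coordinates.
label_trajectory <- function(states, kappa_t, cont, proj) {
  kg <- vapply(cont, function(e) e$kappa, 0)
  z <- states %*% proj$W
  out <- character(nrow(states))
  for (r in seq_len(nrow(states))) {
    e <- cont[[which.min(abs(kg - kappa_t[r]))]]
    if (!nrow(e$states)) { out[r] <- NA_character_; next }
    za <- e$states %*% proj$W
    d2 <- rowSums((za - matrix(z[r, ], nrow(za), 2, byrow = TRUE))^2)
    out[r] <- e$labels[which.min(d2)]
  }
  out
}

# First sustained residence changes along a labelled trajectory.
residence_transitions <- function(times, kappa_t, labels, dwell) {
  keep <- !is.na(labels)
  times <- times[keep]; kappa_t <- kappa_t[keep]; labels <- labels[keep]
  res <- data.frame(time = numeric(0), kappa = numeric(0),
                    from = character(0), to = character(0))
  n <- length(labels)
  if (n < 2) return(res)
  cur <- labels[1]
  i <- 2L
  while (i <= n) {
    if (labels[i] != cur) {
      after <- which(times > times[i] + dwell)
      jend <- if (length(after)) after[1] - 1L else n
      if (all(labels[i:jend] == labels[i])) {
        res <- rbind(res, data.frame(time = times[i], kappa = kappa_t[i],
                                     from = cur, to = labels[i]))
        cur <- labels[i]
        i <- jend + 1L
      } else i <- i + 1L
    } else i <- i + 1L
  }
  res
}

#' Collapse/recovery hysteresis thresholds from ramp ensembles
#'
#' Runs seeded collapse (kappa increasing) and recovery (kappa decreasing)
#' ramps and extracts the per-replicate thresholds: `kappa1` for
#' high/intermediate transitions and `kappa2` for intermediate/low
#' transitions, in each direction. With hysteresis the recovery thresholds
#' sit strictly below the collapse thresholds.
#'
#' @inheritParams ramp_simulation
#' @param kappa_range length-2 range swept by both ramps.
#' @param rate ramp speed (kappa units per time unit).
#' @param n_reps replicates per direction.
#' @return An object of class `hysteresis_report`: data frame `replicates`
#'   (one row per replicate and threshold) and named `medians`
#'   (`kappa1_minus`, `kappa2_minus`, `kappa1_plus`, `kappa2_plus`).
#' @export
hysteresis_experiment <- function(net, params, kappa_range, rate, noise,
                                  n_reps = 20, dt = 0.01, seed = 1,
                                  dwell = 50, record_every = 25,
                                  proj = NULL, n_starts = 30, x_hi = NULL,
                                  kappa_step = 0.01, ...) {
  collapse <- ramp_spec(kappa_range[1], kappa_range[2], rate)
  recovery <- ramp_spec(kappa_range[2], kappa_range[1], rate)
  # shared frozen-parameter structure for the whole ensemble. The
  # continuation is anchored at params$kappa (which should sit inside the
  # multistable window) so that every coexisting branch is tracked across
  # the ramp range, not only those reachable from the sweep edges.
  kgrid <- seq(kappa_range[1], kappa_range[2], by = kappa_step)
  base_mid <- find_attractors(net, params, n_starts = n_starts,
                              seed = seed, x_hi = x_hi)
  cont <- continue_attractors(net, params, kgrid, base = base_mid)
  edge_base <- function(entry, kappa) {
    b <- base_mid
    b$states <- entry$states
    b$labels <- entry$labels
    b$phi <- rep(1 / max(nrow(entry$states), 1), nrow(entry$states))
    b$params <- update_params(params, kappa = kappa)
    b
  }
  base_lo <- edge_base(cont[[1]], kappa_range[1])
  base_hi <- edge_base(cont[[length(cont)]], kappa_range[2])
  if (is.null(proj)) {
    mix0 <- tme_landscape(base_mid, d = max(noise$d, 1e-4))
    proj <- reduce_bipartite(mix0, net)
  }
  rows <- list()
  grab <- function(rr, rep, direction) {
    tr <- rr$transitions
    leave <- function(state) {
      k <- tr$kappa[tr$from == state]
      if (length(k)) k[1] else NA_real_
    }
    arrive <- function(state) {
      k <- tr$kappa[tr$to == state]
      if (length(k)) k[1] else NA_real_
    }
    # kappa1: transition out of / back into the high state; kappa2: into /
    # out of the low state. When the route skips the intermediate state
    # the two thresholds coincide, which is the honest reading of a
    # one-stage transition.
    if (direction == "collapse") {
      data.frame(rep = rep, direction = direction,
                 threshold = c("kappa1_minus", "kappa2_minus"),
                 kappa = c(leave("high"), arrive("low")))
    } else {
      data.frame(rep = rep, direction = direction,
                 threshold = c("kappa2_plus", "kappa1_plus"),
                 kappa = c(leave("low"), arrive("high")))
    }
  }
  for (r in seq_len(n_reps)) {
    rc <- ramp_simulation(net, params, collapse, noise, dt = dt,
                          seed = child_seed(seed, r), dwell = dwell,
                          record_every = record_every, proj = proj,
                          base = base_lo, continuation = cont, ...)
    rows[[length(rows) + 1L]] <- grab(rc, r, "collapse")
    rv <- ramp_simulation(net, params, recovery, noise, dt = dt,
                          seed = child_seed(seed, 10000 + r), dwell = dwell,
                          record_every = record_every, proj = proj,
                          base = base_hi, continuation = cont, ...)
    rows[[length(rows) + 1L]] <- grab(rv, r, "recovery")
  }
  reps <- do.call(rbind, rows)
  med <- vapply(c("kappa1_minus", "kappa2_minus", "kappa1_plus",
                  "kappa2_plus"), function(th)
                    stats::median(reps$kappa[reps$threshold == th],
                                  na.rm = TRUE), 0)
  structure(list(replicates = reps, medians = med),
            class = "hysteresis_report")
}

#' @export
print.hysteresis_report <- function(x, ...) {
  cat("hysteresis_report (ensemble medians):\n")
  for (nm in names(x$medians))
    cat(sprintf("  %-13s %.4f\n", nm, x$medians[nm]))
  invisible(x)
}
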