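# Early-warning-signal engine: RBH sequences over a kappa grid, BDS
# nonlinearity detection, trajectory-based comparators and the
# earliest-warning comparison.

#' Brock-Dechert-Scheinkman (BDS) test of the i.i.d. null
#'
#' Computes the BDS statistic from correlation integrals: for embedding
#' dimension `m` and proximity radius `eps`,
#' `W_m = sqrt(n_m) (C_m - C_1^m) / sigma_m`, asymptotically standard
#' normal under the i.i.d. null. `C_m` is the fraction of embedded point
#' pairs within Chebyshev distance `eps`; `sigma_m` uses the standard
#' asymptotic variance built from the correlation integral `c` and the
#' triple statistic `k`. Rejection indicates serial (typically nonlinear)
#' dependence.
#'
#' The default radius is `1.0 * sd(x)`: at substantially smaller radii the
#' indicator matrix is sparse and the asymptotic normal approximation
#' over-rejects in finite samples. When several embedding dimensions are
#' tested jointly, combine with a Bonferroni factor (as
#' [bds_warning()] does) to keep the nominal size.
#'
#' @param x numeric series.
#' @param m integer vector of embedding dimensions (default `2:3`).
#' @param eps proximity radius; default `1.0 * sd(x)`.
#' @return A data frame with one row per `m`: `m`, `statistic`, `p.value`.
#' @export
bds_test <- function(x, m = 2:3, eps = NULL) {
  n <- length(x)
  stopifnot(n >= 20, all(m >= 2))
  eps <- eps %||% (1.0 * stats::sd(x))
  if (!is.finite(eps) || eps <= 0)
    stop("BDS test undefined: zero-variance series", call. = FALSE)
  I <- abs(outer(x, x, "-")) < eps
  diag(I) <- TRUE
  # correlation integral over all n points and triple statistic k
  rs <- rowSums(I) - 1
  c_full <- sum(rs) / (n * (n - 1))
  k_full <- sum(rs^2 - rs) / (n * (n - 1) * (n - 2))
  rows <- lapply(m, function(mm) {
    nm <- n - mm + 1
    # embedded pair indicator via iterated shifted products
    J <- I[seq_len(nm), seq_len(nm)]
    if (mm > 1) for (off in seq_len(mm - 1)) {
      idx <- off + seq_len(nm)
      J <- J & I[idx, idx]
    }
    Cm <- (sum(J) - nm) / (nm * (nm - 1))
    # first-order integral on the embedded sample (conditioning on the
    # first m-1 observations, Kanzler's convention)
    idx1 <- (mm - 1) + seq_len(nm)
    I1 <- I[idx1, idx1]
    C1 <- (sum(I1) - nm) / (nm * (nm - 1))
    cc <- c_full; kk <- k_full
    j <- seq_len(mm - 1)
    sigma2 <- 4 * (kk^mm +
                     2 * sum(kk^(mm - j) * cc^(2 * j)) +
                     (mm - 1)^2 * cc^(2 * mm) -
                     mm^2 * kk * cc^(2 * mm - 2))
    if (sigma2 <= 0) return(data.frame(m = mm, statistic = NA_real_,
                                       p.value = NA_real_))
    W <- sqrt(nm) * (Cm - C1^mm) / sqrt(sigma2)
    data.frame(m = mm, statistic = W,
               p.value = 2 * stats::pnorm(-abs(W)))
  })
  do.call(rbind, rows)
}

#' RBH sequence over a kappa grid
#'
#' For every `kappa` on the grid, finds the attractors, quantifies the
#' Gaussian-mixture landscape with basin weights recomputed at that point,
#' reduces it with a fixed (shared) projection and reports the relative
#' barrier height between the low and intermediate states. Grid points
#' where either state is missing yield `NA`.
#'
#' @inheritParams glv_drift
#' @param kappa_grid increasing `kappa` values.
#' @param d noise intensity of the landscape.
#' @param proj optional fixed [reduce_bipartite()] projection; when `NULL`
#'   it is computed once at the first grid point exhibiting both states
#'   and reused across the grid, so that all landscapes share coordinates.
#' @param n_starts,seed,x_hi forwarded to [find_attractors()].
#' @param pair the two state labels whose RBH is tracked (default
#'   `c("low", "intermediate")`).
#' @return A data frame of class `rbh_sequence` with columns `kappa`,
#'   `rbh`, `n_states`, `scenario`; the projection is attached as
#'   attribute `proj`.
#' @export
rbh_sequence <- function(net, params, kappa_grid, d = 0.005, proj = NULL,
                         n_starts = 25, seed = 1, x_hi = NULL,
                         pair = c("low", "intermediate")) {
  out <- data.frame(kappa = kappa_grid, rbh = NA_real_,
                    n_states = NA_integer_, scenario = NA_character_)
  for (i in seq_along(kappa_grid)) {
    p <- update_params(params, kappa = kappa_grid[i])
    att <- tryCatch(find_attractors(net, p, n_starts = n_starts,
                                    seed = seed, x_hi = x_hi),
                    error = function(e) NULL)
    if (is.null(att)) next
    out$n_states[i] <- nrow(att$states)
    out$scenario[i] <- att$scenario
    if (!all(pair %in% att$labels)) next
    mix <- tme_landscape(att, d = d)
    if (is.null(proj)) proj <- reduce_bipartite(mix, net)
    red <- reduced_landscape(mix, proj, n_grid = 120)
    # when a label is ambiguous (e.g. two intermediate-like states) take
    # the heavier component
    pick <- vapply(pair, function(lb) {
      k <- which(red$labels == lb)
      if (!length(k)) return(NA_integer_)
      k[which.max(red$weights[k])]
    }, 0L)
    if (any(is.na(pick))) next
    br <- barrier_report(red, pairs = list(pick))
    out$rbh[i] <- br$RBH_ij[1]
  }
  if (sum(!is.na(out$rbh)) < 10)
    warning("fewer than 10 valid RBH points on the grid")
  attr(out, "proj") <- proj
  class(out) <- c("rbh_sequence", class(out))
  out
}

#' BDS warning points along a sequence
#'
#' For each prefix of the sequence (starting at `min_len` points), fits an
#' ordinary least-squares linear trend, applies [bds_test()] to the
#' residuals (Bonferroni-combined p-value over the embedding dimensions,
#' keeping the nominal size of the joint test), and records
#' the first index at which the p-value drops below each significance
#' level. Prefixes with (numerically) zero residual variance are skipped.
#'
#' @param values numeric sequence (e.g. RBH values).
#' @param index optional x-values (e.g. the kappa grid) reported for
#'   warnings; default positions.
#' @param levels significance levels (default `0.05, 0.01, 0.001`).
#' @param min_len minimum prefix length before testing begins (default 15).
#' @param m,eps_factor BDS settings: embedding dimensions and radius as a
#'   fraction of the residual standard deviation.
#' @return A list of class `bds_warnings`: data frame `path` (`index`,
#'   `p.value`) and named vector `warnings` (first index at which each
#'   level is crossed; `NA` when never).
#' @export
bds_warning <- function(values, index = NULL, levels = c(0.05, 0.01, 0.001),
                        min_len = 15, m = 2:3, eps_factor = 1.0) {
  keep <- !is.na(values)
  values <- values[keep]
  index <- (index %||% seq_along(keep))[keep]
  n <- length(values)
  pvals <- rep(NA_real_, n)
  for (k in seq(min_len, n, by = 1)) {
    y <- values[seq_len(k)]
    t <- seq_len(k)
    res <- stats::residuals(stats::lm(y ~ t))
    if (stats::sd(res) < 1e-12 * max(1, max(abs(y)))) next
    b <- tryCatch(bds_test(res, m = m, eps = eps_factor * stats::sd(res)),
                  error = function(e) NULL)
    if (is.null(b)) next
    pvals[k] <- min(1, sum(!is.na(b$p.value)) * min(b$p.value, na.rm = TRUE))
  }
  warn <- vapply(levels, function(lv) {
    hit <- which(pvals < lv)
    if (length(hit)) index[hit[1]] else NA_real_
  }, 0)
  names(warn) <- paste0("p<", levels)
  structure(list(path = data.frame(index = index, p.value = pvals),
                 warnings = warn, levels = levels),
            class = "bds_warnings")
}

# Gaussian kernel smooth of a series (reflective edges).
gaussian_smooth <- function(y, bandwidth) {
  n <- length(y)
  h <- max(bandwidth, 1)
  half <- min(ceiling(4 * h), n - 1)
  w <- stats::dnorm(seq(-half, half), sd = h)
  ypad <- c(rev(y[seq_len(half)]), y, rev(y[n + 1 - seq_len(half)]))
  as.numeric(stats::filter(ypad, w / sum(w), sides = 2))[half + seq_len(n)]
}

#' Trajectory-based early-warning metrics
#'
#' Detrends each species' abundance series by subtracting a Gaussian-kernel
#' smooth, then computes rolling-window metrics: lag-1 autocorrelation
#' (AR(1)) and variance of the residuals, and coefficient of variation
#' (SD/mean) and Fano factor (variance/mean) of the raw window. Windows
#' with an (essentially) zero mean or zero variance yield `NA`.
#'
#' @param states matrix of abundances (time by species) from a Langevin
#'   simulation.
#' @param times recording times.
#' @param window rolling window length in recorded points.
#' @param bandwidth Gaussian filter bandwidth as a fraction of the series
#'   length (default 0.1).
#' @return A list of class `trajectory_metrics` with matrices `ar1`,
#'   `variance`, `cv`, `fano` (rows = window end times, columns = species)
#'   and the vector `times` of window-end times.
#' @export
trajectory_metrics <- function(states, times, window, bandwidth = 0.1) {
  n <- nrow(states)
  stopifnot(window >= 5, window < n)
  h <- bandwidth * n
  resid <- apply(states, 2, function(y) y - gaussian_smooth(y, h))
  ends <- seq(window, n)
  mk <- function(fun) {
    m <- vapply(seq_len(ncol(states)), function(j) {
      vapply(ends, function(e) fun(states[(e - window + 1):e, j],
                                   resid[(e - window + 1):e, j]), 0)
    }, numeric(length(ends)))
    colnames(m) <- colnames(states)
    m
  }
  ar1_fun <- function(raw, rs) {
    if (stats::sd(rs) < 1e-12) return(NA_real_)
    stats::cor(rs[-length(rs)], rs[-1])
  }
  var_fun <- function(raw, rs) stats::var(rs)
  cv_fun <- function(raw, rs) {
    mu <- mean(raw)
    if (abs(mu) < 1e-12) return(NA_real_)
    stats::sd(raw) / mu
  }
  fano_fun <- function(raw, rs) {
    mu <- mean(raw)
    if (abs(mu) < 1e-12) return(NA_real_)
    stats::var(raw) / mu
  }
  structure(list(ar1 = mk(ar1_fun), variance = mk(var_fun),
                 cv = mk(cv_fun), fano = mk(fano_fun),
                 times = times[ends]),
            class = "trajectory_metrics")
}

#' Warning point of a trajectory metric
#'
#' The warning is the smallest control-parameter value from which the
#' (lightly smoothed) metric keeps increasing all the way to the tipping
#' point: small dips up to `slack` times the metric's range are tolerated
#' as stochastic wiggle. Returns `NA` when no such point exists (e.g. a
#' strictly decreasing metric).
#'
#' @param metric numeric metric sequence for one species.
#' @param kappa control-parameter value at each metric point (must be
#'   non-decreasing).
#' @param tipping_kappa kappa of the final collapse (from the ramp).
#' @param smooth_k running-mean half-width used before the monotonicity
#'   scan (default 2).
#' @param slack tolerated relative dip (default 0.05).
#' @return The warning kappa, or `NA`.
#' @export
metric_warning <- function(metric, kappa, tipping_kappa, smooth_k = 2,
                           slack = 0.05) {
  use <- which(kappa <= tipping_kappa & !is.na(metric))
  if (length(use) < 3) return(NA_real_)
  y <- metric[use]; kap <- kappa[use]
  if (smooth_k > 0) {
    w <- rep(1, 2 * smooth_k + 1)
    ys <- as.numeric(stats::filter(y, w / sum(w), sides = 2))
    ys[is.na(ys)] <- y[is.na(ys)]
    y <- ys
  }
  tol <- slack * diff(range(y))
  # from the warning point on, no later value may undercut an earlier one
  # by more than the slack: compare each point against its suffix minimum
  n <- length(y)
  suffix_min <- rev(cummin(rev(y)))
  bad <- which(suffix_min < y - tol)
  start <- if (length(bad)) max(bad) + 1L else 1L
  # a genuine warning requires a net rise from the warning point to the
  # tipping point, not just a flat tail
  if (start >= n || y[n] < y[start] + tol) return(NA_real_)
  kap[start]
}

#' Compare the RBH warning with trajectory-metric warnings
#'
#' Builds the earliest-warning ordering: the BDS warning on the RBH
#' sequence (a single kappa per significance level) against the per-species
#' warnings of each trajectory metric, summarized by their median across
#' species. Smaller kappa means an earlier warning.
#'
#' @param rbh_warn a [bds_warning()] result computed on an RBH sequence
#'   indexed by kappa.
#' @param metrics a [trajectory_metrics()] result from a collapse ramp.
#' @param kappa_t kappa value at each metric time point.
#' @param tipping_kappa kappa of final collapse.
#' @param level which RBH significance level to compare (default 0.05).
#' @return A data frame of class `ews_comparison`: one row per metric with
#'   `median_warning_kappa`, plus the RBH row; ordered by warning kappa.
#' @export
compare_ews <- function(rbh_warn, metrics, kappa_t, tipping_kappa,
                        level = 0.05) {
  rbh_k <- rbh_warn$warnings[paste0("p<", format(level))]
  if (!length(rbh_k)) rbh_k <- rbh_warn$warnings[1]
  rows <- lapply(c("ar1", "variance", "cv", "fano"), function(nm) {
    mm <- metrics[[nm]]
    per_species <- vapply(seq_len(ncol(mm)), function(j)
      metric_warning(mm[, j], kappa_t, tipping_kappa), 0)
    data.frame(signal = nm,
               median_warning_kappa = stats::median(per_species,
                                                    na.rm = TRUE),
               n_species_warning = sum(!is.na(per_species)))
  })
  out <- rbind(data.frame(signal = "RBH",
                          median_warning_kappa = as.numeric(rbh_k),
                          n_species_warning = NA_integer_),
               do.call(rbind, rows))
  out <- out[order(out$median_warning_kappa), ]
  rownames(out) <- NULL
  class(out) <- c("ews_comparison", class(out))
  out
}
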