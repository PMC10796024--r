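#' Model parameters for the mutualistic network dynamics
#'
#' Bundles all rate constants of the generalized Lotka-Volterra mutualism
#' model. Growth, competition and immigration parameters may be scalars
#' (applied to every species) or per-species vectors conforming to the
#' network they are used with. The pollinator decay rate `kappa` is a single
#' scalar applied to all pollinators: it models a global environmental
#' pressure and is the main control parameter of collapse.
#'
#' @param alpha_P,alpha_A intrinsic growth rates of plants / pollinators
#'   (scalar or per-species vector; default 0.3).
#' @param beta_intra_P,beta_intra_A intraspecific competition rates
#'   (default 1).
#' @param beta_inter_P,beta_inter_A interspecific competition rates within
#'   the plant / pollinator guild (default 0.01; assumed much weaker than
#'   intraspecific competition).
#' @param kappa decay rate of pollinators (default 1.07). Normally a single
#'   scalar shared by all pollinators; a per-pollinator vector is accepted
#'   for focal-species perturbation experiments.
#' @param gamma0 per-capita mutualistic strength (default 1).
#' @param delta degree trade-off exponent in `[0, 1]`: 0 means all links
#'   share the same strength, 1 divides the strength fully by the species
#'   degree (default 0.5).
#' @param h half-saturation (handling-time) constant of the Holling type II
#'   mutualistic response (default 0.2).
#' @param mu_P,mu_A immigration rates (default 0). A small constant influx
#'   can be switched on, but the default neglects immigration so that
#'   extinction is absorbing and an extinct species decays below any
#'   positive threshold; with a nonzero `mu` every species is pinned above
#'   `mu / kappa`-scale floors, which is incompatible with an extinction
#'   threshold of `1e-3` at the default rates.
#'
#' @return An object of class `model_params`.
#' @export
#' @examples
#' p <- model_params(kappa = 1.1)
#' p$kappa
model_params <- function(alpha_P = 0.3, alpha_A = 0.3,
                         beta_intra_P = 1, beta_intra_A = 1,
                         beta_inter_P = 0.01, beta_inter_A = 0.01,
                         kappa = 1.07, gamma0 = 1, delta = 0.5,
                         h = 0.2, mu_P = 0, mu_A = 0) {
  p <- list(alpha_P = alpha_P, alpha_A = alpha_A,
            beta_intra_P = beta_intra_P, beta_intra_A = beta_intra_A,
            beta_inter_P = beta_inter_P, beta_inter_A = beta_inter_A,
            kappa = kappa, gamma0 = gamma0, delta = delta,
            h = h, mu_P = mu_P, mu_A = mu_A)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || any(!is.finite(v)) || any(v < 0))
      stop(sprintf("parameter '%s' must be finite and non-negative", nm),
           call. = FALSE)
  }
  if (p$delta > 1) stop("delta must lie in [0, 1]", call. = FALSE)
  # kappa is normally a single scalar (global environmental decay); a
  # per-pollinator vector is accepted for focal-species perturbations.
  for (nm in c("gamma0", "delta", "h"))
    if (length(p[[nm]]) != 1L)
      stop(sprintf("parameter '%s' must be scalar", nm), call. = FALSE)
  class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("Mutualistic GLV model parameters\n")
  for (nm in names(unclass(x))) {
    v <- x[[nm]]
    cat(sprintf("  %-13s %s\n", nm,
                if (length(v) == 1L) format(v)
                else sprintf("per-species vector [%d]", length(v))))
  }
  invisible(x)
}

#' Modify a subset of model parameters
#'
#' @param params a [model_params()] object.
#' @param ... named parameters to replace.
#' @return A new `model_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "model_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), names(unclass(params)))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  p <- unclass(params)
  p[names(repl)] <- repl
  do.call(model_params, p)
}

# Expand a scalar-or-vector parameter to length n, with dimension checking.
expand_param <- function(v, n, name) {
  if (length(v) == 1L) return(rep(v, n))
  if (length(v) != n) stop_dim(name, n, length(v))
  v
}

# Resolve all per-species parameter vectors against a network.
resolve_params <- function(params, net) {
  stopifnot(inherits(params, "model_params"),
            inherits(net, "bipartite_network"))
  np <- net$n_plants; na <- net$n_pollinators
  list(alpha_P = expand_param(params$alpha_P, np, "alpha_P"),
       alpha_A = expand_param(params$alpha_A, na, "alpha_A"),
       beta_intra_P = expand_param(params$beta_intra_P, np, "beta_intra_P"),
       beta_intra_A = expand_param(params$beta_intra_A, na, "beta_intra_A"),
       beta_inter_P = expand_param(params$beta_inter_P, np, "beta_inter_P"),
       beta_inter_A = expand_param(params$beta_inter_A, na, "beta_inter_A"),
       kappa = expand_param(params$kappa, na, "kappa"),
       gamma0 = params$gamma0, delta = params$delta, h = params$h,
       mu_P = expand_param(params$mu_P, np, "mu_P"),
       mu_A = expand_param(params$mu_A, na, "mu_A"))
}
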