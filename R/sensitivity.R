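# One-at-a-time global sensitivity analysis: +/-10% perturbations of each
# rate (globally, and for the focal pollinator that survives alone in the
# intermediate state), scored by the relative change of minimum transition
# actions between state pairs.

#' Default perturbation design
#'
#' Global parameters are perturbed in the direction that pushes the system
#' toward collapse (growth rates and mutualistic strength down; competition,
#' decay, handling time and degree trade-off up) or toward recovery (the
#' opposite signs). Starred entries perturb only the focal pollinator.
#'
#' @param direction `"collapse"` or `"recovery"`.
#' @param size perturbation magnitude (default 0.1 = 10%).
#' @return Data frame with `parameter`, `factor` (multiplier), `focal`
#'   (logical).
#' @export
perturbation_design <- function(direction = c("collapse", "recovery"),
                                size = 0.1) {
  direction <- match.arg(direction)
  down <- c("alpha_P", "alpha_A", "gamma0", "alpha_star", "gamma0_star")
  up <- c("beta_intra_P", "beta_intra_A", "kappa", "h", "delta",
          "beta_star", "kappa_star")
  sgn <- if (direction == "collapse") 1 else -1
  rbind(
    data.frame(parameter = down, factor = 1 - sgn * size,
               focal = grepl("_star$", down)),
    data.frame(parameter = up, factor = 1 + sgn * size,
               focal = grepl("_star$", up)))
}

# Apply one perturbation, returning list(params, gammas). Starred
# parameters touch only the focal pollinator; gamma0 / gamma0_star act
# through the strength matrices.
apply_perturbation <- function(net, params, parameter, factor, focal_idx) {
  na <- net$n_pollinators
  p <- params
  gam <- NULL
  if (parameter %in% c("alpha_P", "alpha_A", "beta_intra_P",
                       "beta_intra_A", "kappa", "h", "delta", "gamma0")) {
    args <- list(params)
    args[[parameter]] <- params[[parameter]] * factor
    p <- do.call(update_params, args)
  } else {
    base <- switch(parameter,
                   alpha_star = "alpha_A", beta_star = "beta_intra_A",
                   kappa_star = "kappa",
                   gamma0_star = "gamma0")
    if (parameter == "gamma0_star") {
      gam <- build_gamma(net, params)
      gam$gamma_PA[, focal_idx] <- gam$gamma_PA[, focal_idx] * factor
      gam$gamma_AP[focal_idx, ] <- gam$gamma_AP[focal_idx, ] * factor
    } else {
      v <- expand_param(params[[base]], na, base)
      v[focal_idx] <- v[focal_idx] * factor
      args <- list(params)
      args[[base]] <- v
      p <- do.call(update_params, args)
    }
  }
  list(params = p, gammas = gam)
}

#' Global sensitivity of transition actions to parameter perturbations
#'
#' Starting from a tristable baseline, each design entry perturbs one
#' parameter by the design factor, recomputes the attractors and the
#' minimum transition actions for the requested state pairs, and reports
#' the relative change `(S_pert - S_base) / S_base`. When a perturbation
#' destroys a state, the action toward the vanished state is 0 and the
#' action away from it infinite; the relative changes are encoded as `-1`
#' and a display cap (default 2.5), with the raw situation preserved in
#' the `vanished` flag.
#'
#' @inheritParams glv_drift
#' @param design data frame from [perturbation_design()] (or both
#'   directions row-bound; the default uses the collapse design on the
#'   intermediate/low pair and the recovery design on the
#'   high/intermediate pair).
#' @param focal focal pollinator index; default the pollinator surviving
#'   in the intermediate state (max degree among survivors as tie-break).
#' @param pairs list of state-label pairs to score per direction.
#' @param n_starts,seed,x_hi attractor-search settings.
#' @param L,T_schedule path-optimization settings (kept modest: the
#'   actions enter as ratios).
#' @param inf_cap display encoding of an infinite relative change.
#' @return Data frame of class `sensitivity_report`: `parameter`,
#'   `direction`, `factor`, `pair`, `S_base`, `S_pert`, `rel_change`,
#'   `vanished`.
#' @export
run_sensitivity <- function(net, params, design = NULL, focal = NULL,
                            n_starts = 60, seed = 1, x_hi = 1,
                            L = 14, T_schedule = c(30, 60), inf_cap = 2.5,
                            gammas = NULL) {
  att <- find_attractors(net, params, n_starts = n_starts, seed = seed,
                         x_hi = x_hi, gammas = gammas)
  if (!all(c("high", "intermediate", "low") %in% att$labels))
    stop("baseline system is not tristable (scenario ", att$scenario, ")",
         call. = FALSE)
  if (is.null(focal)) {
    ia <- net$n_plants + seq_len(net$n_pollinators)
    int_state <- att$states[att$labels == "intermediate", ][ia]
    alive <- which(int_state >= att$extinction_threshold)
    focal <- alive[which.max(pollinator_degrees(net)[alive])]
  }
  base_states <- att$states
  rownames(base_states) <- att$labels
  base_actions <- new.env()
  get_action <- function(states, labels, from, to, p, gam) {
    xi <- states[labels == from, , drop = FALSE]
    xj <- states[labels == to, , drop = FALSE]
    if (!nrow(xi) || !nrow(xj)) return(NA_real_)
    transition_path(net, p, xi[1, ], xj[1, ], gammas = gam, L = L,
                    T_schedule = T_schedule)$action
  }
  if (is.null(design)) {
    design <- rbind(cbind(perturbation_design("collapse"),
                          direction = "collapse"),
                    cbind(perturbation_design("recovery"),
                          direction = "recovery"))
  } else if (is.null(design$direction)) {
    design$direction <- "collapse"
  }
  rows <- list()
  for (r in seq_len(nrow(design))) {
    pr <- apply_perturbation(net, params, design$parameter[r],
                             design$factor[r], focal)
    patt <- tryCatch(find_attractors(net, pr$params, n_starts = n_starts,
                                     seed = seed, x_hi = x_hi,
                                     gammas = pr$gammas),
                     error = function(e) NULL)
    pair <- if (design$direction[r] == "collapse")
      c("intermediate", "low") else c("high", "intermediate")
    key <- paste(pair, collapse = ">")
    if (is.null(base_actions[[key]])) {
      base_actions[[key]] <- c(
        fwd = get_action(base_states, att$labels, pair[1], pair[2],
                         params, gammas),
        bwd = get_action(base_states, att$labels, pair[2], pair[1],
                         params, gammas))
    }
    Sb <- base_actions[[key]]
    for (leg in c("fwd", "bwd")) {
      pp <- if (leg == "fwd") pair else rev(pair)
      vanished <- is.null(patt) || !all(pp %in% patt$labels)
      if (!vanished) {
        Sp <- get_action(patt$states, patt$labels, pp[1], pp[2],
                         pr$params, pr$gammas)
        rel <- (Sp - Sb[[leg]]) / Sb[[leg]]
      } else {
        # which state vanished decides the encoding
        to_gone <- is.null(patt) || !(pp[2] %in% patt$labels)
        Sp <- if (to_gone) 0 else Inf
        rel <- if (to_gone) -1 else inf_cap
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = design$parameter[r], direction = design$direction[r],
        factor = design$factor[r],
        pair = paste(pp, collapse = "->"),
        S_base = Sb[[leg]], S_pert = Sp, rel_change = rel,
        vanished = vanished)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "focal") <- focal
  class(out) <- c("sensitivity_report", class(out))
  out
}
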