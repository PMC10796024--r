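#' Synthetic tristable fixture network
#'
#' A packaged, fully reproducible synthetic plant-pollinator system that
#' exhibits tristability: a 17 x 61 random bipartite network (connectance
#' 0.12, degree heterogeneity 1.2, generator seed 31) reduced by random
#' removal of 80% of its pollinators (removal seed 5031) to 17 plants and
#' 13 pollinators. At the fixture parameters (defaults with
#' `kappa = 1.05`) the system has exactly three stable states: a high
#' state (10 pollinators alive), an intermediate state in which only the
#' most generalist pollinator (degree 8) survives with plants at moderate
#' abundance, and a low state with every pollinator extinct. By
#' continuation, the high and low states coexist for `kappa` in about
#' `[1.00, 1.035]`, all three for `kappa` in about `[1.04, 1.085]`, and
#' only the low state above about `1.09`.
#'
#' Attractor searches on this network should sample initial conditions
#' from `[0, 1]` per species (`x_hi = 1`, the fixture default): the
#' low/intermediate basins occupy a negligible share of the wider default
#' box, while under `x_hi = 1` all three basins carry substantial weight
#' (about 0.52 / 0.33 / 0.14 for high / intermediate / low at
#' `kappa = 1.05`).
#'
#' This is a synthetic stand-in constructed by a seeded search (random
#' 17 x 61-like networks, random removals, scanning `kappa`); it is not an
#' empirical network. The same incidence matrix ships as a delimited file
#' at `system.file("extdata", "fixture_tristable_synthetic.csv",
#' package = "ecoscape")` for use with [read_network()].
#'
#' @param kappa decay rate of the fixture parameter set (default 1.05).
#' @return A list with `net` (a [bipartite_network()]), `params`
#'   (a [model_params()]), and `x_hi` (recommended initial-condition box
#'   upper bound, 1).
#' @export
#' @examples
#' \donttest{
#' fx <- fixture_tristable()
#' att <- find_attractors(fx$net, fx$params, n_starts = 100, seed = 1,
#'                        x_hi = fx$x_hi)
#' att$scenario  # "HIL"
#' }
fixture_tristable <- function(kappa = 1.05) {
  base <- generate_network(17, 61, connectance = 0.12,
                           heterogeneity = 1.2, seed = 31)
  net <- remove_pollinators(base, 0.8, seed = 5031)
  list(net = net, params = model_params(kappa = kappa), x_hi = 1)
}

#' Small bistable toy system (one plant, one pollinator)
#'
#' A minimal network used in oracles and sweeps: a single plant-pollinator
#' pair whose high (both alive) and low (pollinator extinct) states
#' coexist over a window of `kappa`, providing a cheap bistable system for
#' Kramers-law, hysteresis and colored-noise experiments. At the defaults
#' (`gamma0 = 2.5`) the closed-form window of coexistence is
#' `kappa` in about `(0.95, 1.82)`: the low state stabilizes once the
#' pollinator's invasion growth rate at the plant carrying capacity turns
#' negative, and the high state disappears at the saddle-node of the
#' interior equilibria.
#'
#' @param kappa decay rate (default 1.3, inside the bistable window at the
#'   other defaults).
#' @param gamma0 per-capita mutualistic strength (default 2.5).
#' @return A list with `net`, `params`, `x_hi`.
#' @export
toy_bistable <- function(kappa = 1.3, gamma0 = 2.5) {
  net <- bipartite_network(matrix(1, 1, 1))
  list(net = net,
       params = model_params(kappa = kappa, gamma0 = gamma0),
       x_hi = 2)
}
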