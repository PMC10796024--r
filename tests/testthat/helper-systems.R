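# Shared systems and lazily cached expensive objects.

# tiny deterministic 3x2 network used across parser/gamma tests
tiny_net <- function() {
  bipartite_network(matrix(c(1, 0,
                             1, 1,
                             0, 1), 3, 2, byrow = TRUE))
}

# cache expensive fixture computations once per test process
.cache <- new.env(parent = emptyenv())

fixture_attractors <- function() {
  if (is.null(.cache$fx_att)) {
    fx <- fixture_tristable()
    .cache$fx <- fx
    .cache$fx_att <- find_attractors(fx$net, fx$params, n_starts = 80,
                                     seed = 1, x_hi = fx$x_hi)
  }
  .cache$fx_att
}

fixture_system <- function() {
  fixture_attractors()
  .cache$fx
}

# 1-D double well f = x - x^3 used by the action oracles
dw_f <- function(x) x - x^3
dw_jac <- function(x) matrix(1 - 3 * x^2, 1, 1)
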