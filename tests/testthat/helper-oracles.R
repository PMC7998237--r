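# Shared fixtures and independent numerical oracles.

# default exponential-survival games used across tests
iso_game <- function(...) gamete_game(alpha = 1, beta = 2, M = 10, ...)
aniso_game <- function(...) gamete_game(alpha = 1, beta = 8, M = 10, ...)

# threshold gamete survival + power-law zygote survival
power_game <- function(h = 1.5, k = 1, delta = 1e-3, M = 1) {
  gamete_game(M = M, alpha = 0, beta = 0, k = k, c = 1, h = h,
              delta = delta, gamete_survival = "threshold",
              zygote_survival = "power")
}

# central finite-difference oracle for the selection gradient
fd_gradient <- function(x, y, game, eps = 1e-6) {
  ex <- eps * max(1, abs(x))
  ey <- eps * max(1, abs(y))
  c(x = (log_fitness(x + ex, y, game) -
           log_fitness(x - ex, y, game)) / (2 * ex),
    y = (log_fitness(y + ey, x, game) -
           log_fitness(y - ey, x, game)) / (2 * ey))
}

# central finite-difference oracle for the gradient-system Jacobian
fd_jacobian <- function(x, y, game, eps = 1e-6) {
  ex <- eps * max(1, abs(x))
  ey <- eps * max(1, abs(y))
  gx_p <- selection_gradient(x + ex, y, game)
  gx_m <- selection_gradient(x - ex, y, game)
  gy_p <- selection_gradient(x, y + ey, game)
  gy_m <- selection_gradient(x, y - ey, game)
  cbind((gx_p - gx_m) / (2 * ex), (gy_p - gy_m) / (2 * ey))
}
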