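# Adaptive-dynamics integration: gradient ascent of the two gamete sizes
# on the log-fitness landscape, with boundary clamping.

#' Integrate adaptive dynamics of the two gamete sizes
#'
#' Explicit Euler integration of the trait dynamics
#' `dx/dt = d ln w_x/d x`, `dy/dt = d ln w_y/d y` (the canonical-equation
#' prefactor of mutational variance and population size is set to 1, so
#' time units are arbitrary; the log-fitness gradient is used because it
#' is the correct measure of the magnitude of evolutionary change).
#' Coordinates are clamped to `[delta, M]` under the threshold
#' gamete-survival form and to `(0, M]` otherwise.
#'
#' Integration stops early when the projected gradient norm falls below
#' `grad_tol` — the gradient component of a coordinate pinned at a bound
#' with outward-pointing selection counts as zero, so boundary outcomes
#' (e.g. oogamy-like `x -> M`, `y -> delta` in the power-law variant)
#' are recognised as converged.
#'
#' Exactly symmetric starts (`x == y`) stay on the diagonal forever, so
#' to observe the symmetry-broken anisogamous outcome start slightly off
#' the diagonal; which coordinate starts larger determines which mating
#' type becomes the macrogamete producer.
#'
#' @param game A [gamete_game()].
#' @param start Numeric `c(x, y)` initial sizes (within bounds).
#' @param step Positive Euler step in trait units per unit gradient. The
#'   default is `0.01 * min(alpha, beta)` for the exponential forms and
#'   `0.01 * M` otherwise.
#' @param max_steps Maximum number of Euler steps.
#' @param grad_tol Projected-gradient convergence tolerance.
#' @return An object of class `"gamete_trajectory"`: a list with
#'   `times`, `x`, `y` (the path), `converged`, `final_residual` (the
#'   projected gradient norm at the last state), and `game`.
#' @examples
#' tr <- evolve_trajectory(gamete_game(alpha = 1, beta = 8, M = 10),
#'                         start = c(3, 1))
#' tail(as.data.frame(tr), 1) # approaches (6.828, 1.172)
#' @export
evolve_trajectory <- function(game, start, step = NULL, max_steps = 200000L,
                              grad_tol = 1e-9) {
  stopifnot(inherits(game, "gamete_game"), is.numeric(start),
            length(start) == 2L, all(start > 0))
  if (is.null(step)) {
    step <- if (game$zygote_survival == "exponential" &&
                game$alpha > 0 && game$beta > 0) {
      0.01 * min(game$alpha, game$beta)
    } else {
      0.01 * game$M
    }
  }
  if (!is.numeric(step) || length(step) != 1L || step <= 0) {
    stop("`step` must be a positive number (got ", step, ")")
  }
  lower <- if (game$gamete_survival == "threshold") game$delta
           else .Machine$double.eps
  upper <- game$M
  p <- pmin(pmax(start, lower), upper)
  xs <- numeric(max_steps + 1L)
  ys <- numeric(max_steps + 1L)
  xs[1L] <- p[1]; ys[1L] <- p[2]
  proj_norm <- function(p, g) {
    out <- (p <= lower & g < 0) | (p >= upper & g > 0)
    g[out] <- 0
    max(abs(g))
  }
  n_rec <- 1L
  converged <- FALSE
  grad <- function(p) c(.dlogw(p[1], p[2], game), .dlogw(p[2], p[1], game))
  g <- grad(p)
  for (i in seq_len(max_steps)) {
    if (any(!is.finite(g))) {
      stop("non-finite gradient at (", p[1], ", ", p[2],
           ") after ", i - 1L, " steps")
    }
    if (proj_norm(p, g) < grad_tol) { converged <- TRUE; break }
    p <- pmin(pmax(p + step * g, lower), upper)
    n_rec <- n_rec + 1L
    xs[n_rec] <- p[1]; ys[n_rec] <- p[2]
    g <- grad(p)
  }
  if (!converged && proj_norm(p, g) < grad_tol) converged <- TRUE
  structure(
    list(times = step * (seq_len(n_rec) - 1L),
         x = xs[seq_len(n_rec)], y = ys[seq_len(n_rec)],
         converged = converged,
         final_residual = proj_norm(p, g),
         step = step, game = game),
    class = "gamete_trajectory"
  )
}

#' @export
print.gamete_trajectory <- function(x, ...) {
  n <- length(x$times)
  cat(sprintf(
    "Adaptive-dynamics trajectory: %d steps, %sconverged (residual %.3g)\n",
    n - 1L, if (x$converged) "" else "NOT ", x$final_residual))
  cat(sprintf("  start (%.6g, %.6g) -> end (%.6g, %.6g)\n",
              x$x[1], x$y[1], x$x[n], x$y[n]))
  invisible(x)
}

#' @export
as.data.frame.gamete_trajectory <- function(x, ...) {
  data.frame(t = x$times, x = x$x, y = x$y)
}

#' Phase-plane plot of an adaptive-dynamics trajectory
#'
#' Plots the path in the `(x, y)` trait plane with the start marked by an
#' open circle and the end by a filled one; the isogamy diagonal is drawn
#' dashed.
#'
#' @param x A `gamete_trajectory`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.gamete_trajectory <- function(x, ...) {
  rng <- range(c(x$x, x$y))
  graphics::plot(x$x, x$y, type = "l", xlab = "gamete size x",
                 ylab = "gamete size y", xlim = rng, ylim = rng, ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  n <- length(x$x)
  graphics::points(x$x[1], x$y[1], pch = 1)
  graphics::points(x$x[n], x$y[n], pch = 16)
  invisible(x)
}
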