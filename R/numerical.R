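# Numerical oracle: Newton root finding on the selection-gradient system,
# convergence-stability and invasibility classification, and bisection
# detection of regime thresholds.

# one damped-Newton run; returns list(x, y, residual, converged)
.newton_root <- function(game, start, tol = 1e-12, max_iter = 200L) {
  lower <- if (game$gamete_survival == "threshold") game$delta else 1e-12
  p <- unname(pmax(start, lower))
  g <- unname(selection_gradient(p[1], p[2], game))
  res <- max(abs(g))
  # polish well past the acceptance residual: quadratic convergence makes
  # the extra iterations free and pins the position to ~1e-12 relative
  target <- min(tol, 1e-15)
  for (i in seq_len(max_iter)) {
    if (res < target) break
    J <- gradient_jacobian(p[1], p[2], game)
    step <- tryCatch(unname(solve(J, -g)), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    lambda <- 1
    repeat {
      cand <- p + lambda * step
      ok <- all(cand > lower)
      if (ok) {
        gc2 <- unname(selection_gradient(cand[1], cand[2], game))
        if (all(is.finite(gc2)) && max(abs(gc2)) < res) {
          p <- cand; g <- gc2; res <- max(abs(g))
          break
        }
      }
      lambda <- lambda / 2
      if (lambda < 1e-12) break
    }
    if (lambda < 1e-12) break
  }
  list(x = p[1], y = p[2], residual = res, converged = res < tol)
}

#' Numerically solve the selection-gradient system
#'
#' Finds a root of `(d ln w_x/d x, d ln w_y/d y) = (0, 0)` by damped
#' Newton iteration with the closed-form Jacobian. This is the
#' independent numerical oracle against which the closed-form equilibria
#' are checked.
#'
#' If `start` is given, the root reached from that start is returned as
#' found (so asymmetric starts recover either labelling of the
#' anisogamous pair). If `start = NULL`, a deterministic multistart set
#' is used — the diagonal point plus two strongly asymmetric corners
#' `(0.9*M, 2*delta)` and `(2*delta, 0.9*M)` — and among the distinct
#' roots found the convergence-stable one (leading Jacobian eigenvalue
#' negative) is returned, with the macrogamete reported first.
#'
#' @param game A [gamete_game()].
#' @param start Optional numeric `c(x, y)` initial point.
#' @param tol Residual tolerance on the gradient components.
#' @param max_iter Maximum Newton iterations per start.
#' @return A `gamete_equilibrium` with `source = "numerical"`.
#' @examples
#' solve_equilibrium(gamete_game(alpha = 1, beta = 8), start = c(6, 1))
#' @export
solve_equilibrium <- function(game, start = NULL, tol = 1e-10,
                              max_iter = 200L) {
  stopifnot(inherits(game, "gamete_game"))
  same <- function(a, b) abs(a - b) < 1e-7 * max(1, abs(a), abs(b))
  if (!is.null(start)) {
    stopifnot(is.numeric(start), length(start) == 2L, all(start > 0))
    r <- .newton_root(game, start, tol, max_iter)
    if (!r$converged) {
      stop("root finder did not converge from (", start[1], ", ", start[2],
           "); best residual ", signif(r$residual, 3))
    }
    regime <- if (same(r$x, r$y)) "isogamy" else "anisogamy"
    return(new_equilibrium(r$x, r$y, regime, "numerical", game))
  }
  m <- if (game$gamete_survival == "exponential" &&
           game$zygote_survival == "exponential") {
    game$k * (game$alpha + game$beta / 4)
  } else {
    sqrt(game$delta * game$M)
  }
  starts <- list(c(m, m),
                 c(0.9 * game$M, 2 * game$delta),
                 c(2 * game$delta, 0.9 * game$M))
  if (game$gamete_survival == "exponential" &&
      game$zygote_survival == "exponential" &&
      game$beta > 4 * game$alpha) {
    # binomial-approximation guess homes in on the anisogamous root
    ap <- game$k * c(game$beta - game$alpha, game$alpha)
    starts <- c(starts, list(ap, rev(ap)))
  }
  roots <- list()
  for (s in starts) {
    r <- tryCatch(.newton_root(game, s, tol, max_iter),
                  error = function(e) NULL)
    if (is.null(r) || !r$converged) next
    dup <- any(vapply(roots, function(q) {
      same(q$x, r$x) && same(q$y, r$y)
    }, logical(1)))
    if (!dup) roots[[length(roots) + 1L]] <- r
  }
  if (length(roots) == 0L) {
    stop("root finder did not converge from any start point")
  }
  pick <- NULL
  for (r in roots) {
    ev <- eigen(gradient_jacobian(r$x, r$y, game),
                only.values = TRUE)$values
    if (max(Re(ev)) < 0) { pick <- r; break }
  }
  if (is.null(pick)) pick <- roots[[1L]]
  hi <- max(pick$x, pick$y); lo <- min(pick$x, pick$y)
  regime <- if (same(hi, lo)) "isogamy" else "anisogamy"
  new_equilibrium(hi, lo, regime, "numerical", game)
}

#' Invasion gain of a rare mutant against a resident population
#'
#' Log-fitness advantage of a rare mutant of the given mating type:
#' `ln w_role(mutant, resident_partner) - ln w_role(resident_own,
#' resident_partner)`. Positive gain means the mutant invades; the gain
#' is exactly 0 when the mutant equals the resident. `-Inf` marks
#' inviable mutants under the threshold gamete-survival form.
#'
#' @param mutant Positive mutant gamete size(s); vectorized.
#' @param resident Numeric `c(x, y)` resident sizes.
#' @param role `"x"` or `"y"`: the mating type the mutant belongs to.
#' @param game A [gamete_game()].
#' @return Numeric invasion gain(s).
#' @export
invasion_gain <- function(mutant, resident, role = c("x", "y"), game) {
  role <- match.arg(role)
  stopifnot(inherits(game, "gamete_game"), is.numeric(mutant),
            is.numeric(resident), length(resident) == 2L)
  own <- if (role == "x") resident[1] else resident[2]
  partner <- if (role == "x") resident[2] else resident[1]
  log_fitness(mutant, partner, game) - log_fitness(own, partner, game)
}

# log-spaced mutant grid over [delta, M]
.mutant_grid <- function(game, n = 400L) {
  exp(seq(log(game$delta), log(game$M), length.out = n))
}

#' Stability classification at an equilibrium
#'
#' Two complementary assessments at a gradient root:
#'
#' * convergence stability: both eigenvalues of the closed-form Jacobian
#'   of the gradient system (see [gradient_jacobian()]) have real part
#'   below `-tol_eigen`, so gradual evolution approaches the point;
#' * global non-invasibility (ESS sense): no mutant on a log-spaced size
#'   grid over `[delta, M]`, in either mating-type role, has
#'   [invasion_gain()] above `tol_invasion`.
#'
#' Both are reported because they can disagree: a convergence-stable but
#' invadable point is an evolutionary branching point
#' (`branching_flag`), and in the power-law variant the interior root is
#' a repeller so only the global scan is informative.
#'
#' @param game A [gamete_game()].
#' @param point Numeric `c(x, y)`, an equilibrium (gradient residual
#'   below `1e-8`, checked).
#' @param grid_points Mutant-scan grid size.
#' @param tol_eigen Eigenvalue sign deadband.
#' @param tol_invasion Invasion-gain positivity deadband.
#' @return A list of class `"stability_record"`: `jacobian`,
#'   `eigenvalues` (sorted by decreasing real part),
#'   `convergence_stable`, `globally_uninvadable`, `branching_flag`.
#' @export
stability_at <- function(game, point, grid_points = 400L,
                         tol_eigen = 1e-9, tol_invasion = 1e-9) {
  stopifnot(inherits(game, "gamete_game"), is.numeric(point),
            length(point) == 2L)
  g <- selection_gradient(point[1], point[2], game)
  if (max(abs(g)) > 1e-8) {
    stop("`point` is not an equilibrium: gradient residual ",
         signif(max(abs(g)), 3), " > 1e-8")
  }
  J <- gradient_jacobian(point[1], point[2], game)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(Re(ev), decreasing = TRUE)]
  grid <- .mutant_grid(game, grid_points)
  gains <- c(invasion_gain(grid, point, "x", game),
             invasion_gain(grid, point, "y", game))
  structure(
    list(jacobian = J, eigenvalues = ev,
         convergence_stable = all(Re(ev) < -tol_eigen),
         globally_uninvadable = max(gains) <= tol_invasion,
         branching_flag = all(Re(ev) < -tol_eigen) &&
           max(gains) > tol_invasion),
    class = "stability_record"
  )
}

#' @export
print.stability_record <- function(x, ...) {
  cat(sprintf("Stability: eigenvalues (%.6g, %.6g)\n",
              Re(x$eigenvalues[1]), Re(x$eigenvalues[2])))
  cat(sprintf("  convergence stable: %s; globally uninvadable: %s%s\n",
              x$convergence_stable, x$globally_uninvadable,
              if (x$branching_flag) "; BRANCHING POINT" else ""))
  invisible(x)
}

# leading Jacobian eigenvalue at the closed-form isogamous equilibrium,
# from log or absolute fitness gradients (signs agree: at the symmetric
# point the absolute-gradient Jacobian is the log one scaled by w > 0)
.iso_leading_eigenvalue <- function(game, fitness_scale = "log") {
  m <- game$k * (game$alpha + game$beta / 4)
  J <- gradient_jacobian(m, m, game)
  if (fitness_scale == "absolute") {
    J <- diag(c(fitness(m, m, game), fitness(m, m, game))) %*% J
  }
  max(Re(eigen(J, only.values = TRUE)$values))
}

#' Locate a regime threshold by bisection
#'
#' Bisects a single model parameter on a boolean regime criterion:
#'
#' * `criterion = "isogamy_destabilised"` (parameter `"beta"`,
#'   exponential forms): the leading eigenvalue of the gradient-system
#'   Jacobian at the closed-form isogamous equilibrium crosses zero —
#'   isogamy turns from an attractor into a saddle with a disruptive
#'   direction. The detected critical value is `4*alpha`, independent of
#'   `k` and of whether gradients are taken from log or absolute fitness.
#' * `criterion = "boundary_invadable"` (parameter `"h"`, power-law
#'   zygote survival with threshold gamete survival): some mutant on a
#'   log grid over `[delta, M]` gains positive invasion fitness against
#'   the minimal-size isogamous resident `(delta, delta)`.
#'
#' Note that for `"boundary_invadable"` the detected critical exponent at
#' finite `delta` is `ln(M/delta) / (k * ln((M+delta)/(2*delta)))`, which
#' converges to `1/k` only as `delta/M -> 0`; see
#' [asymptotic_h_threshold()] for the limit measurement.
#'
#' @param game A [gamete_game()]; the scanned parameter is overridden.
#' @param parameter `"beta"` or `"h"`.
#' @param bracket Numeric length-2 bracket; the criterion must change
#'   truth value across it.
#' @param criterion `"isogamy_destabilised"` or `"boundary_invadable"`.
#' @param tol Bisection bracket-width tolerance.
#' @param grid_points Mutant-grid size for the invasibility criterion.
#' @param fitness_scale `"log"` or `"absolute"` gradient convention for
#'   the eigenvalue criterion (thresholds are identical).
#' @return A list of class `"threshold_scan"`: `parameter`, `criterion`,
#'   `critical_value` (bracket midpoint), `bracket` (final), `iterations`,
#'   and `trace` (a data frame of evaluated parameter values with the
#'   regime label at each).
#' @examples
#' find_threshold(gamete_game(alpha = 1), "beta", c(1, 10),
#'                "isogamy_destabilised")
#' @export
find_threshold <- function(game,
                           parameter = c("beta", "h"),
                           bracket,
                           criterion = c("isogamy_destabilised",
                                         "boundary_invadable"),
                           tol = 1e-6, grid_points = 400L,
                           fitness_scale = c("log", "absolute")) {
  parameter <- match.arg(parameter)
  criterion <- match.arg(criterion)
  fitness_scale <- match.arg(fitness_scale)
  stopifnot(inherits(game, "gamete_game"), is.numeric(bracket),
            length(bracket) == 2L, bracket[1] < bracket[2], tol > 0)
  crit <- function(value) {
    g2 <- if (parameter == "beta") update_game(game, beta = value)
          else update_game(game, h = value)
    if (criterion == "isogamy_destabilised") {
      .iso_leading_eigenvalue(g2, fitness_scale) > 0
    } else {
      grid <- .mutant_grid(g2, grid_points)
      resident <- c(g2$delta, g2$delta)
      max(invasion_gain(grid, resident, "x", g2)) > 1e-12
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  f_lo <- crit(lo); f_hi <- crit(hi)
  if (f_lo == f_hi) {
    stop("criterion does not change across the bracket [", lo, ", ", hi,
         "]; no threshold to bisect")
  }
  trace_val <- c(lo, hi)
  trace_reg <- c(f_lo, f_hi)
  iterations <- 0L
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    f_mid <- crit(mid)
    trace_val <- c(trace_val, mid)
    trace_reg <- c(trace_reg, f_mid)
    if (f_mid == f_lo) lo <- mid else hi <- mid
    iterations <- iterations + 1L
  }
  structure(
    list(parameter = parameter, criterion = criterion,
         critical_value = (lo + hi) / 2, bracket = c(lo, hi),
         iterations = iterations,
         trace = data.frame(
           value = trace_val,
           regime = ifelse(trace_reg, "anisogamy", "isogamy"),
           stringsAsFactors = FALSE)),
    class = "threshold_scan"
  )
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf(
    "Threshold scan on %s (%s): critical value %.8g after %d bisections\n",
    x$parameter, x$criterion, x$critical_value, x$iterations))
  cat(sprintf("  final bracket [%.8g, %.8g]\n", x$bracket[1], x$bracket[2]))
  invisible(x)
}

#' Asymptotic invasibility threshold for the power-law exponent
#'
#' The condition for anisogamy under power-law zygote survival with a
#' threshold minimum gamete size — `h*k > 1` — is a statement about the
#' limit of vanishing minimum size: at any finite `delta` the
#' boundary-invasibility threshold detected by [find_threshold()] is
#' biased upward, with closed form
#' `h_crit(delta) = ln(M/delta) / (k * ln((M+delta)/(2*delta)))`
#' (the binding mutant puts the whole budget into one gamete of size
#' `M`). The bias is `~ln(2) / ln(M/delta)`, so this function runs the
#' bisection at a decreasing sequence of `delta` values and extrapolates
#' the measured thresholds in `u = 1/ln(M/delta)` to `u = 0` with a
#' polynomial fit of degree `length(deltas) - 1`, recovering the
#' asymptotic critical exponent `1/k` to better than `1e-3` with the
#' default sequence.
#'
#' @param game A [gamete_game()] with power-law zygote survival; `delta`
#'   is overridden by `deltas`.
#' @param bracket Bisection bracket for `h` (applied at every `delta`).
#' @param deltas Decreasing sequence of minimum gamete sizes.
#' @param tol Bisection tolerance passed to [find_threshold()].
#' @param grid_points Mutant-grid size.
#' @return A list with `h_crit` (extrapolated), `finite` (data frame of
#'   per-`delta` measured thresholds), and `scans` (the underlying
#'   `threshold_scan` objects).
#' @export
asymptotic_h_threshold <- function(game, bracket = c(0.25, 2),
                                   deltas = c(1e-6, 1e-9, 1e-12),
                                   tol = 1e-8, grid_points = 400L) {
  stopifnot(inherits(game, "gamete_game"),
            game$zygote_survival == "power", length(deltas) >= 2L)
  scans <- lapply(deltas, function(d) {
    find_threshold(update_game(game, delta = d), "h", bracket,
                   "boundary_invadable", tol = tol,
                   grid_points = grid_points)
  })
  hs <- vapply(scans, function(s) s$critical_value, numeric(1))
  u <- 1 / log(game$M / deltas)
  fit <- stats::lm(hs ~ stats::poly(u, degree = length(deltas) - 1L,
                                    raw = TRUE))
  h_crit <- unname(stats::coef(fit)[1])
  list(h_crit = h_crit,
       finite = data.frame(delta = deltas, u = u, h_crit = hs),
       scans = scans)
}
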