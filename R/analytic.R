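# Closed-form equilibria of the exponential-survival game and derived
# quantities (size ratios, regime classification).

# internal constructor; x, y given in reported order
new_equilibrium <- function(x, y, regime, source, game) {
  g <- selection_gradient(x, y, game)
  structure(
    list(x = x, y = y, regime = regime, source = source,
         gradient_residual = max(abs(g)), stability = NULL, game = game),
    class = "gamete_equilibrium"
  )
}

#' @export
print.gamete_equilibrium <- function(x, ...) {
  cat(sprintf("Equilibrium (%s, %s): x = %.8g, y = %.8g\n",
              x$regime, x$source, x$x, x$y))
  cat(sprintf("  size ratio x/y = %.8g, gradient residual = %.3g\n",
              max(x$x, x$y) / min(x$x, x$y), x$gradient_residual))
  if (!is.null(x$stability)) print(x$stability)
  invisible(x)
}

#' @export
as.data.frame.gamete_equilibrium <- function(x, ...) {
  data.frame(alpha = x$game$alpha, beta = x$game$beta, k = x$game$k,
             regime = x$regime, x = x$x, y = x$y,
             ratio = max(x$x, x$y) / min(x$x, x$y), source = x$source,
             stringsAsFactors = FALSE)
}

#' @export
print.no_anisogamy <- function(x, ...) {
  cat(sprintf(
    "No real anisogamous solution: beta = %g <= 4 * alpha = %g\n",
    x$beta, 4 * x$alpha))
  invisible(x)
}

.require_exponential <- function(game, what) {
  if (game$gamete_survival != "exponential" ||
      game$zygote_survival != "exponential") {
    stop(what, " requires the exponential survival forms")
  }
}

#' Closed-form isogamous equilibrium
#'
#' For the exponential survival forms the isogamous singular point is
#' `x = y = k * (alpha + beta/4)`. Returned with no stability claim:
#' the point is convergence stable only for `beta <= 4 * alpha` (see
#' [stability_at()]).
#'
#' @param game A [gamete_game()] with exponential survival forms.
#' @return A `gamete_equilibrium` with `regime = "isogamy"`,
#'   `source = "closed_form"`.
#' @examples
#' isogamous_equilibrium(gamete_game(alpha = 1, beta = 2)) # x = y = 1.5
#' @export
isogamous_equilibrium <- function(game) {
  stopifnot(inherits(game, "gamete_game"))
  .require_exponential(game, "isogamous_equilibrium()")
  m <- game$k * (game$alpha + game$beta / 4)
  new_equilibrium(m, m, "isogamy", "closed_form", game)
}

#' Closed-form anisogamous equilibrium
#'
#' For the exponential survival forms and `beta > 4 * alpha` the
#' anisogamous equilibrium is the root pair of the quadratic obtained
#' under the sum constraint `x + y = k * beta`:
#' `x = (k*beta/2) * (1 + sqrt(1 - 4*alpha/beta))` (macrogamete) and
#' `y = k*beta - x` (microgamete). The two quadratic roots are the macro-
#' and microgamete sizes; which mating type carries which label is
#' historical (see [evolve_trajectory()]) and here the macrogamete is
#' arbitrarily assigned to `x`.
#'
#' When `beta <= 4 * alpha` the quadratic has no real asymmetric root and
#' an object of class `"no_anisogamy"` is returned (a marker, not an
#' error).
#'
#' @inheritParams isogamous_equilibrium
#' @return A `gamete_equilibrium` (`regime = "anisogamy"`) or a
#'   `"no_anisogamy"` marker.
#' @export
anisogamous_equilibrium <- function(game) {
  stopifnot(inherits(game, "gamete_game"))
  .require_exponential(game, "anisogamous_equilibrium()")
  if (game$beta <= 4 * game$alpha) {
    return(structure(list(alpha = game$alpha, beta = game$beta),
                     class = "no_anisogamy"))
  }
  disc <- sqrt(1 - 4 * game$alpha / game$beta)
  x <- game$k * game$beta / 2 * (1 + disc)
  y <- game$k * game$beta - x
  new_equilibrium(x, y, "anisogamy", "closed_form", game)
}

#' The stable equilibrium of the exponential-survival game
#'
#' Piecewise closed form: the isogamous branch
#' `x = y = k*(alpha + beta/4)` for `beta <= 4*alpha`, the anisogamous
#' branch for `beta > 4*alpha`. The two branches coincide (both equal
#' `2*k*alpha`) at the threshold `beta = 4*alpha`, so the stable
#' equilibrium is continuous in `(alpha, beta)`.
#'
#' @inheritParams isogamous_equilibrium
#' @return A `gamete_equilibrium`.
#' @export
stable_equilibrium <- function(game) {
  stopifnot(inherits(game, "gamete_game"))
  .require_exponential(game, "stable_equilibrium()")
  if (game$beta <= 4 * game$alpha) {
    isogamous_equilibrium(game)
  } else {
    anisogamous_equilibrium(game)
  }
}

#' Binomial-approximation anisogamous equilibrium
#'
#' First-order (binomial) approximation of the square root in the exact
#' anisogamous solution gives `(x, y) ~ (k*(beta - alpha), k*alpha)`.
#' Accurate for `beta >> 4*alpha` but grossly inaccurate near the
#' threshold, where it produces a spurious discontinuity in the gamete
#' size ratio (the ratio jumps to `beta/alpha - 1 = 3` at onset instead
#' of rising continuously from 1). Returned with
#' `source = "approximation"`.
#'
#' @inheritParams isogamous_equilibrium
#' @return A `gamete_equilibrium` or a `"no_anisogamy"` marker when
#'   `beta <= 4*alpha`.
#' @export
approximate_equilibrium <- function(game) {
  stopifnot(inherits(game, "gamete_game"))
  .require_exponential(game, "approximate_equilibrium()")
  if (game$beta <= 4 * game$alpha) {
    return(structure(list(alpha = game$alpha, beta = game$beta),
                     class = "no_anisogamy"))
  }
  new_equilibrium(game$k * (game$beta - game$alpha), game$k * game$alpha,
                  "anisogamy", "approximation", game)
}

#' Macrogamete:microgamete size ratio at equilibrium
#'
#' Exact method: 1 for `beta <= 4*alpha`, otherwise
#' `(1 + s)/(1 - s)` with `s = sqrt(1 - 4*alpha/beta)` — continuous,
#' `>= 1`, strictly increasing in `beta/alpha` and unbounded.
#' Approximate method: 1 strictly below the threshold,
#' `beta/alpha - 1` from the threshold up — discontinuous at onset,
#' jumping from 1 straight to 3 (the anisogamous branch of the
#' approximation is assigned the tie so the curve displays the onset
#' value of that branch). The ratio depends only on `beta/alpha`: both
#' `k` and `M` cancel.
#'
#' @inheritParams isogamous_equilibrium
#' @param method `"exact"` or `"approximate"`.
#' @return Numeric ratio `>= 1`.
#' @examples
#' size_ratio(gamete_game(alpha = 1, beta = 8), "exact") # 3 + 2*sqrt(2)
#' @export
size_ratio <- function(game, method = c("exact", "approximate")) {
  method <- match.arg(method)
  stopifnot(inherits(game, "gamete_game"))
  .require_exponential(game, "size_ratio()")
  if (method == "exact") {
    if (game$beta <= 4 * game$alpha) return(1)
    s <- sqrt(1 - 4 * game$alpha / game$beta)
    (1 + s) / (1 - s)
  } else {
    if (game$beta < 4 * game$alpha) return(1)
    game$beta / game$alpha - 1
  }
}

#' Classify the evolutionary regime and report the analytic threshold
#'
#' For the exponential zygote-survival form the outcome is anisogamy if
#' and only if `beta > 4*alpha`; the threshold `beta_crit = 4*alpha` is
#' independent of the trade-off exponent `k`. For the power-law form
#' (threshold gamete survival) anisogamy is possible if and only if
#' `h*k > 1`, i.e. the critical exponent is `h_crit = 1/k` — with an
#' inefficient trade-off (`k > 1`) even a linear or concave zygote
#' survival can generate anisogamy. Equality is classified as isogamy
#' (the branches coincide there).
#'
#' @param game A [gamete_game()].
#' @return A list of class `"regime_classification"` with elements
#'   `regime` (`"isogamy"` or `"anisogamy"`), `parameter` (`"beta"` or
#'   `"h"`), and `threshold` (the analytic critical value).
#' @export
classify_regime <- function(game) {
  stopifnot(inherits(game, "gamete_game"))
  if (game$zygote_survival == "exponential") {
    res <- list(
      regime = if (game$beta > 4 * game$alpha) "anisogamy" else "isogamy",
      parameter = "beta",
      threshold = 4 * game$alpha
    )
  } else {
    res <- list(
      regime = if (game$h * game$k > 1) "anisogamy" else "isogamy",
      parameter = "h",
      threshold = 1 / game$k
    )
  }
  structure(res, class = "regime_classification")
}

#' @export
print.regime_classification <- function(x, ...) {
  cat(sprintf("Regime: %s (critical %s = %g)\n",
              x$regime, x$parameter, x$threshold))
  invisible(x)
}
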