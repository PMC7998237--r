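#' Construct a gamete-size game
#'
#' A `gamete_game` object bundles every parameter of the two-mating-type
#' gamete size game: a parent with resource budget `M` divides it into
#' gametes of size `x` (mating type x) or `y` (mating type y); gametes of
#' opposite type fuse to form zygotes. Fitness of a type is
#' `w = n * g * f`, the product of gamete number (size-number trade-off),
#' gamete survival, and zygote survival.
#'
#' Two functional forms are available for each survival component:
#'
#' * gamete survival: `"exponential"`, `g(x) = exp(-alpha/x)`, or
#'   `"threshold"`, a step function in which every gamete at or above the
#'   minimum viable size `delta` survives and smaller gametes die.
#' * zygote survival: `"exponential"`, `f(x, y) = exp(-beta/(x+y))`, or
#'   `"power"`, `f(x, y) = c * (x + y)^h` (a fitness factor, not capped
#'   at 1).
#'
#' The trade-off exponent `k >= 1` generalizes the exact trade-off
#' `n = M/x` to `n = (M/x)^(1/k)`; values `k > 1` model resource lost
#' during successive gamete-producing divisions (see
#' [division_tradeoff()]).
#'
#' @param M Positive total gametic resource budget per parent (mass units).
#' @param alpha Nonnegative gamete-survival scale (same units as gamete
#'   size). Larger `alpha` means small gametes die faster.
#' @param beta Nonnegative zygote-survival scale (same units as gamete
#'   size). Larger `beta` means zygote survival depends more strongly on
#'   provisioning.
#' @param k Trade-off inefficiency exponent, `k >= 1` (dimensionless);
#'   `k = 1` is the exact size-number trade-off.
#' @param c Positive proportionality constant of the power-law zygote
#'   survival.
#' @param h Positive power-law zygote-survival exponent (dimensionless).
#' @param delta Positive minimum viable gamete size (size units), used by
#'   the threshold gamete-survival form and as the lower bound of mutant
#'   scans; must satisfy `delta < M`.
#' @param gamete_survival One of `"exponential"`, `"threshold"`.
#' @param zygote_survival One of `"exponential"`, `"power"`.
#'
#' @return An object of class `"gamete_game"`: a named list of validated
#'   parameters.
#' @seealso [log_fitness()], [selection_gradient()], [stable_equilibrium()]
#' @examples
#' game <- gamete_game(alpha = 1, beta = 8)
#' stable_equilibrium(game)
#' @export
gamete_game <- function(M = 10, alpha = 1, beta = 2, k = 1, c = 1, h = 1,
                        delta = 1e-3,
                        gamete_survival = c("exponential", "threshold"),
                        zygote_survival = c("exponential", "power")) {
  gamete_survival <- match.arg(gamete_survival)
  zygote_survival <- match.arg(zygote_survival)
  stopifnot(
    is.numeric(M), length(M) == 1L, is.finite(M),
    is.numeric(alpha), length(alpha) == 1L, is.finite(alpha),
    is.numeric(beta), length(beta) == 1L, is.finite(beta),
    is.numeric(k), length(k) == 1L, is.finite(k),
    is.numeric(c), length(c) == 1L, is.finite(c),
    is.numeric(h), length(h) == 1L, is.finite(h),
    is.numeric(delta), length(delta) == 1L, is.finite(delta)
  )
  if (M <= 0) stop("`M` must be > 0 (got ", M, ")")
  if (alpha < 0) stop("`alpha` must be >= 0 (got ", alpha, ")")
  if (beta < 0) stop("`beta` must be >= 0 (got ", beta, ")")
  if (k < 1) stop("`k` must be >= 1 (got ", k, ")")
  if (c <= 0) stop("`c` must be > 0 (got ", c, ")")
  if (h <= 0) stop("`h` must be > 0 (got ", h, ")")
  if (delta <= 0) stop("`delta` must be > 0 (got ", delta, ")")
  if (delta >= M) stop("`delta` must be < `M` (got delta = ", delta,
                       ", M = ", M, ")")
  structure(
    list(M = M, alpha = alpha, beta = beta, k = k, c = c, h = h,
         delta = delta,
         gamete_survival = gamete_survival,
         zygote_survival = zygote_survival),
    class = "gamete_game"
  )
}

#' @export
print.gamete_game <- function(x, ...) {
  cat("Gamete-size game\n")
  cat(sprintf("  budget M = %g, trade-off exponent k = %g\n", x$M, x$k))
  cat(sprintf("  gamete survival: %s (alpha = %g, delta = %g)\n",
              x$gamete_survival, x$alpha, x$delta))
  cat(sprintf("  zygote survival: %s (beta = %g, c = %g, h = %g)\n",
              x$zygote_survival, x$beta, x$c, x$h))
  invisible(x)
}

#' Modify parameters of an existing game
#'
#' Returns a new validated [gamete_game()] with the supplied parameters
#' replaced. Used heavily by parameter scans.
#'
#' @param game A `gamete_game`.
#' @param ... Named parameters to replace (any argument of [gamete_game()]).
#' @return A new `gamete_game`.
#' @export
update_game <- function(game, ...) {
  stopifnot(inherits(game, "gamete_game"))
  new <- utils::modifyList(unclass(game), list(...))
  gamete_game(M = new$M, alpha = new$alpha, beta = new$beta, k = new$k,
              c = new$c, h = new$h, delta = new$delta,
              gamete_survival = new$gamete_survival,
              zygote_survival = new$zygote_survival)
}

# unconstrained gamete number: (M/x)^(1/k); no upper bound on x so that
# fitness can be evaluated at k-scaled equilibria exceeding M
.gamete_number <- function(x, game) (game$M / x)^(1 / game$k)

#' Gamete number from the size-number trade-off
#'
#' Number of gametes `n = (M/x)^(1/k)` a parent produces at gamete size
#' `x`. With an exact trade-off (`k = 1`) this is `M/x`; `k > 1` models an
#' inefficient division process. Strictly decreasing in `x`, with
#' `n(M) = 1`.
#'
#' @param x Gamete size(s), `0 < x <= M`.
#' @param game A [gamete_game()].
#' @return Gamete number(s), positive.
#' @examples
#' gamete_number(4, gamete_game(M = 100, k = 2)) # (100/4)^(1/2) = 5
#' @export
gamete_number <- function(x, game) {
  stopifnot(inherits(game, "gamete_game"), is.numeric(x))
  if (any(x <= 0)) stop("gamete size must be > 0 (got ", min(x), ")")
  if (any(x > game$M)) stop("gamete size must be <= M = ", game$M,
                            " (got ", max(x), ")")
  .gamete_number(x, game)
}

#' Cell-division reparametrisation of the size-number trade-off
#'
#' The trade-off `x = M / n^k` has a concrete biological reading: after
#' `d` rounds of binary division a parent holds `n = 2^d` gametes of size
#' `x = M * q^d / 2^d`, where `q = 2^(1-k)` is the fraction of the
#' gametic resource retained at each division round (`1 - q` is lost to
#' the division process). `k = 1` (`q = 1`) is lossless halving.
#'
#' @param k Trade-off exponent, `>= 1`.
#' @param d Nonnegative integer number of binary division rounds.
#' @param M Positive resource budget.
#' @return A list of class `"division_tradeoff"` with elements `q`, `d`,
#'   `n = 2^d`, `x`, and `k` (recovered from `q` as `1 - log2(q)`, an
#'   exact round trip).
#' @examples
#' division_tradeoff(k = 2, d = 2, M = 8) # q = 0.5, n = 4, x = 0.5
#' @export
division_tradeoff <- function(k, d, M) {
  stopifnot(is.numeric(k), length(k) == 1L, is.numeric(d), length(d) == 1L,
            is.numeric(M), length(M) == 1L, M > 0)
  if (k < 1) stop("`k` must be >= 1 (got ", k, ")")
  if (d < 0 || d != round(d)) stop("`d` must be a nonnegative integer")
  q <- 2^(1 - k)
  n <- 2^d
  x <- M * q^d / n
  structure(list(q = q, d = d, n = n, x = x, k = 1 - log2(q)),
            class = "division_tradeoff")
}

#' @export
print.division_tradeoff <- function(x, ...) {
  cat(sprintf(
    "Division trade-off: d = %d rounds, retained fraction q = %g (k = %g)\n",
    x$d, x$q, x$k))
  cat(sprintf("  n = %g gametes of size x = %g\n", x$n, x$x))
  invisible(x)
}

#' Gamete survival
#'
#' Survival probability of a gamete of given size: `exp(-alpha/size)`
#' under the exponential form (increasing in size), or a step function
#' under the threshold form (1 at or above the minimum viable size
#' `delta`, 0 below it).
#'
#' @param size Positive gamete size(s).
#' @param game A [gamete_game()].
#' @return Survival probability in `[0, 1]`.
#' @export
gamete_survival <- function(size, game) {
  stopifnot(inherits(game, "gamete_game"), is.numeric(size))
  if (any(size <= 0)) stop("gamete size must be > 0 (got ", min(size), ")")
  switch(game$gamete_survival,
    exponential = exp(-game$alpha / size),
    threshold = as.numeric(size >= game$delta)
  )
}

#' Zygote survival
#'
#' Survival of a zygote provisioned by gametes of sizes `x` and `y`:
#' `exp(-beta/(x+y))` under the exponential form (a probability), or the
#' power law `c * (x+y)^h` (a fitness factor that may exceed 1; eventual
#' saturation is not needed for the qualitative results and is not
#' imposed).
#'
#' @param x,y Positive gamete sizes of the two fusing gametes.
#' @param game A [gamete_game()].
#' @return Positive survival value(s).
#' @export
zygote_survival <- function(x, y, game) {
  stopifnot(inherits(game, "gamete_game"), is.numeric(x), is.numeric(y))
  if (any(x <= 0)) stop("gamete size x must be > 0 (got ", min(x), ")")
  if (any(y <= 0)) stop("gamete size y must be > 0 (got ", min(y), ")")
  s <- x + y
  switch(game$zygote_survival,
    exponential = exp(-game$beta / s),
    power = game$c * s^game$h
  )
}

#' Log fitness of a focal mating type
#'
#' Log fitness `ln w = ln n(focal) + ln g(focal) + ln f(focal, partner)`
#' of a parent producing gametes of size `focal` whose gametes fuse with
#' partner gametes of size `partner`. The same function serves both
#' mating types with the arguments swapped. For the exponential survival
#' forms this is
#' `(1/k) * (ln M - ln focal) - alpha/focal - beta/(focal + partner)`.
#'
#' Under the threshold gamete-survival form a focal size below `delta`
#' returns `-Inf` (inviable gametes; an absorbing worst case for
#' optimizers), which is deliberately distinct from a domain error.
#'
#' Note that `focal` is not required to be `<= M`: the `k`-scaled
#' equilibria can exceed the budget, in which case `n < 1` simply scales
#' fitness down. The hard bound is enforced where it matters, in
#' [gamete_number()], trajectory clamping and mutant scans.
#'
#' @param focal Positive focal gamete size(s).
#' @param partner Positive partner gamete size(s).
#' @param game A [gamete_game()].
#' @return Log fitness; `-Inf` for inviable focal gametes under the
#'   threshold form.
#' @seealso [fitness()], [selection_gradient()]
#' @export
log_fitness <- function(focal, partner, game) {
  stopifnot(inherits(game, "gamete_game"), is.numeric(focal),
            is.numeric(partner))
  if (any(focal <= 0)) stop("focal gamete size must be > 0 (got ",
                            min(focal), ")")
  if (any(partner <= 0)) stop("partner gamete size must be > 0 (got ",
                              min(partner), ")")
  ln_n <- (log(game$M) - log(focal)) / game$k
  ln_g <- switch(game$gamete_survival,
    exponential = -game$alpha / focal,
    threshold = ifelse(focal >= game$delta, 0, -Inf)
  )
  s <- focal + partner
  ln_f <- switch(game$zygote_survival,
    exponential = -game$beta / s,
    power = log(game$c) + game$h * log(s)
  )
  ln_n + ln_g + ln_f
}

#' Absolute fitness of a focal mating type
#'
#' `exp(log_fitness(focal, partner, game))`; see [log_fitness()].
#'
#' @inheritParams log_fitness
#' @return Fitness `w = n * g * f` (0 for inviable threshold-form
#'   gametes).
#' @export
fitness <- function(focal, partner, game) {
  exp(log_fitness(focal, partner, game))
}

# derivative of log fitness with respect to the focal size, closed form
.dlogw <- function(focal, partner, game) {
  d <- -1 / (game$k * focal)
  if (game$gamete_survival == "exponential") {
    d <- d + game$alpha / focal^2
  } else if (any(focal < game$delta)) {
    stop("selection gradient undefined for inviable gametes ",
         "(size < delta = ", game$delta, ")")
  }
  s <- focal + partner
  d + switch(game$zygote_survival,
    exponential = game$beta / s^2,
    power = game$h / s
  )
}

#' Selection gradient at a resident strategy pair
#'
#' Closed-form selection gradient
#' `(d ln w_x / d x, d ln w_y / d y)` evaluated at the resident pair
#' `(x, y)`. Both components vanish at evolutionary equilibria. With
#' `type = "absolute"` the gradient of absolute fitness
#' `w * d ln w / d x` is returned instead; the two conventions share the
#' same zero set wherever fitness is positive (only the magnitude of
#' evolutionary change differs, for which the log-fitness gradient is the
#' appropriate measure).
#'
#' @param x,y Positive resident gamete sizes of mating types x and y.
#' @param game A [gamete_game()].
#' @param type `"log"` (default) or `"absolute"` fitness derivative.
#' @return Named numeric vector `c(x = ..., y = ...)`.
#' @examples
#' g <- gamete_game(alpha = 1, beta = 2)
#' selection_gradient(1.5, 1.5, g) # (0, 0): the isogamous equilibrium
#' @export
selection_gradient <- function(x, y, game, type = c("log", "absolute")) {
  type <- match.arg(type)
  stopifnot(inherits(game, "gamete_game"),
            is.numeric(x), length(x) == 1L,
            is.numeric(y), length(y) == 1L)
  if (x <= 0 || y <= 0) stop("gamete sizes must be > 0 (got x = ", x,
                             ", y = ", y, ")")
  g <- c(x = .dlogw(x, y, game), y = .dlogw(y, x, game))
  if (type == "absolute") {
    g <- g * c(fitness(x, y, game), fitness(y, x, game))
  }
  g
}

#' Jacobian of the selection-gradient system
#'
#' The 2x2 Jacobian of `(d ln w_x/d x, d ln w_y/d y)` with respect to
#' `(x, y)`, assembled from closed-form second derivatives. Its
#' eigenvalues at an equilibrium classify convergence stability (see
#' [stability_at()]).
#'
#' @inheritParams selection_gradient
#' @return A 2x2 numeric matrix.
#' @export
gradient_jacobian <- function(x, y, game) {
  stopifnot(inherits(game, "gamete_game"),
            is.numeric(x), length(x) == 1L,
            is.numeric(y), length(y) == 1L, x > 0, y > 0)
  s <- x + y
  # zygote-survival second derivatives are identical in xx, yy and cross
  f2 <- switch(game$zygote_survival,
    exponential = -2 * game$beta / s^3,
    power = -game$h / s^2
  )
  g2x <- switch(game$gamete_survival,
    exponential = -2 * game$alpha / x^3,
    threshold = 0
  )
  g2y <- switch(game$gamete_survival,
    exponential = -2 * game$alpha / y^3,
    threshold = 0
  )
  j11 <- 1 / (game$k * x^2) + g2x + f2
  j22 <- 1 / (game$k * y^2) + g2y + f2
  matrix(c(j11, f2, f2, j22), nrow = 2, byrow = TRUE,
         dimnames = list(c("x", "y"), c("x", "y")))
}

#' Read or write a game configuration as flat JSON
#'
#' The configuration is a flat JSON object with keys exactly
#' `M, alpha, beta, k, c, h, delta, gamete_survival_form,
#' zygote_survival_form`.
#'
#' @param game A [gamete_game()].
#' @param path File path.
#' @return `write_game_config()` returns `path` invisibly;
#'   `read_game_config()` returns a `gamete_game`.
#' @export
write_game_config <- function(game, path) {
  stopifnot(inherits(game, "gamete_game"))
  cfg <- list(M = game$M, alpha = game$alpha, beta = game$beta, k = game$k,
              c = game$c, h = game$h, delta = game$delta,
              gamete_survival_form = game$gamete_survival,
              zygote_survival_form = game$zygote_survival)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_game_config
#' @export
read_game_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  num <- function(v) as.numeric(v) # JSON integers parse as integer
  gamete_game(M = num(cfg$M), alpha = num(cfg$alpha), beta = num(cfg$beta),
              k = num(cfg$k), c = num(cfg$c), h = num(cfg$h),
              delta = num(cfg$delta),
              gamete_survival = cfg$gamete_survival_form,
              zygote_survival = cfg$zygote_survival_form)
}
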