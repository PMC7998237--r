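# Fisher-consistent fitness with per-gamete fertilization probabilities
# and pluggable fertilization-count models.

#' Define a fertilization-count model
#'
#' A fertilization model maps the gamete numbers of the two mating types
#' to the number of fertilizations `F`, subject to the mass-balance
#' contract `0 <= F <= min(n_x, n_y)` and symmetry in `(n_x, n_y)`
#' (each zygote uses exactly one gamete of each type). Per-gamete
#' fertilization probabilities are then derived as `p_x = F/n_x`,
#' `p_y = F/n_y`, which enforces the Fisher condition
#' `p_x * n_x = p_y * n_y = F` by construction rather than by assumption.
#'
#' Two built-ins ship: [complete_fertilization()] (`F = min(n_x, n_y)`,
#' every gamete of the rarer type is fertilized) and
#' [saturating_fertilization()] (`F = n_x*n_y / (n_x + n_y + s)`, a
#' smooth saturating kinetic with half-saturation offset `s >= 0`).
#' These are illustrative contracts, not endorsements of any particular
#' fertilization-kinetics model; users can register any count function
#' obeying the contract.
#'
#' @param name Identifier string.
#' @param count_function Function of `(n_x, n_y)` returning `F`.
#' @return A list of class `"fertilization_model"`.
#' @export
fertilization_model <- function(name, count_function) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(count_function))
  structure(list(name = name, count_function = count_function),
            class = "fertilization_model")
}

#' @export
print.fertilization_model <- function(x, ...) {
  cat(sprintf("Fertilization model: %s\n", x$name))
  invisible(x)
}

#' @rdname fertilization_model
#' @export
complete_fertilization <- function() {
  fertilization_model("complete", function(n_x, n_y) pmin(n_x, n_y))
}

#' @rdname fertilization_model
#' @param s Nonnegative saturation offset of the saturating kinetic.
#' @export
saturating_fertilization <- function(s = 0) {
  stopifnot(is.numeric(s), length(s) == 1L, s >= 0)
  fertilization_model(
    sprintf("saturating(s=%g)", s),
    function(n_x, n_y) n_x * n_y / (n_x + n_y + s)
  )
}

#' Per-gamete fertilization probabilities
#'
#' Evaluates the fertilization count `F` and derives `p_x = F/n_x`,
#' `p_y = F/n_y`. The model contract (`0 <= F <= min(n_x, n_y)`,
#' symmetry) is checked and violations raise an error.
#'
#' @param n_x,n_y Positive gamete numbers of the two mating types.
#' @param model A [fertilization_model()].
#' @return A list with `p_x`, `p_y` (in `[0, 1]`) and `F`; by
#'   construction `p_x * n_x == p_y * n_y == F`.
#' @examples
#' fertilization_probabilities(10, 4, complete_fertilization())
#' @export
fertilization_probabilities <- function(n_x, n_y, model) {
  stopifnot(inherits(model, "fertilization_model"),
            is.numeric(n_x), is.numeric(n_y))
  if (any(n_x <= 0) || any(n_y <= 0)) {
    stop("gamete numbers must be > 0")
  }
  F <- model$count_function(n_x, n_y)
  F_swap <- model$count_function(n_y, n_x)
  tol <- 1e-12 * pmax(1, pmin(n_x, n_y))
  if (any(F < -tol) || any(F > pmin(n_x, n_y) + tol)) {
    stop("fertilization model '", model$name,
         "' violates 0 <= F <= min(n_x, n_y)")
  }
  if (any(abs(F - F_swap) > tol)) {
    stop("fertilization model '", model$name,
         "' is not symmetric in (n_x, n_y)")
  }
  list(p_x = F / n_x, p_y = F / n_y, F = F)
}

# fertilization-weighted log fitness components for a concrete pair
.limited_components <- function(x, y, game, model) {
  n_x <- .gamete_number(x, game)
  n_y <- .gamete_number(y, game)
  pr <- fertilization_probabilities(n_x, n_y, model)
  list(
    n_x = n_x, n_y = n_y, p_x = pr$p_x, p_y = pr$p_y, F = pr$F,
    lw_x = log(pr$p_x) + log(n_x) + log(gamete_survival(x, game)) +
      log(zygote_survival(x, y, game)),
    lw_y = log(pr$p_y) + log(n_y) + log(gamete_survival(y, game)) +
      log(zygote_survival(x, y, game))
  )
}

#' Fisher-consistent (gamete-limited) fitness
#'
#' Fitness with an explicit per-gamete fertilization probability,
#' `w_x = p_x * n_x * g_x * f(x, y)` and likewise for `y`. Because
#' `p = F/n`, the combined reproductive output of the two types is equal
#' (`p_x * n_x = p_y * n_y = F`) at every strategy pair — the Fisher
#' condition holds by construction, unlike the bare fitness `n * g * f`
#' whose type totals differ whenever gamete numbers do.
#'
#' @param x,y Positive resident gamete sizes.
#' @param game A [gamete_game()].
#' @param model A [fertilization_model()].
#' @return A list of class `"limited_fitness"` with `w_x`, `w_y`
#'   (absolute), `log_w_x`, `log_w_y`, `p_x`, `p_y`, `F`, and
#'   `fisher_gap = |p_x n_x - p_y n_y|` (zero to machine precision).
#' @export
limited_log_fitness <- function(x, y, game, model) {
  stopifnot(inherits(game, "gamete_game"), x > 0, y > 0)
  cmp <- .limited_components(x, y, game, model)
  structure(
    list(w_x = exp(cmp$lw_x), w_y = exp(cmp$lw_y),
         log_w_x = cmp$lw_x, log_w_y = cmp$lw_y,
         p_x = cmp$p_x, p_y = cmp$p_y, F = cmp$F,
         fisher_gap = abs(cmp$p_x * cmp$n_x - cmp$p_y * cmp$n_y)),
    class = "limited_fitness"
  )
}

#' @export
print.limited_fitness <- function(x, ...) {
  cat(sprintf("Gamete-limited fitness: w_x = %.6g, w_y = %.6g\n",
              x$w_x, x$w_y))
  cat(sprintf("  p_x = %.6g, p_y = %.6g, F = %.6g, Fisher gap = %.3g\n",
              x$p_x, x$p_y, x$F, x$fisher_gap))
  invisible(x)
}

#' Selection gradient under gamete limitation
#'
#' Selection gradient of the fertilization-weighted log fitness with
#' respect to a rare mutant's own gamete size, under two population
#' structures:
#'
#' * `"panmictic"`: gametes mix over a very large population, so a rare
#'   mutant's output does not move the per-gamete fertilization
#'   probabilities; `p_x`, `p_y` are held fixed at their resident values
#'   when differentiating. The gradient then equals the base-model
#'   [selection_gradient()] (the log of a constant drops out), so the
#'   equilibria are unchanged by adding fertilization probability — the
#'   apparent Fisher-condition paradox of the bare model has no
#'   consequence under panmixia, however severe the gamete limitation.
#' * `"local_group"`: the minimal group-structured case of one focal pair
#'   per group, in which the mutant's own gamete number shifts the local
#'   fertilization count, so `p` varies with the mutant and the gradient
#'   generally differs from the base model.
#'
#' Derivatives are computed by central finite differences of the mutant
#' log fitness (step `1e-6` relative), since fertilization-count models
#' are pluggable user functions with no closed-form derivative contract.
#'
#' @inheritParams limited_log_fitness
#' @param structure `"panmictic"` or `"local_group"`.
#' @return Named numeric vector `c(x = ..., y = ...)`.
#' @export
limited_selection_gradient <- function(x, y, game, model,
                                       structure = c("panmictic",
                                                     "local_group")) {
  structure <- match.arg(structure)
  stopifnot(inherits(game, "gamete_game"), x > 0, y > 0)
  res <- .limited_components(x, y, game, model)
  mutant_lw <- function(size, role) {
    n_mut <- .gamete_number(size, game)
    if (structure == "panmictic") {
      p <- if (role == "x") res$p_x else res$p_y
    } else {
      # mutant's own output shifts the local fertilization count
      F_mut <- if (role == "x") model$count_function(n_mut, res$n_y)
               else model$count_function(res$n_x, n_mut)
      p <- F_mut / n_mut
    }
    partner <- if (role == "x") y else x
    log(p) + log(n_mut) + log(gamete_survival(size, game)) +
      log(zygote_survival(size, partner, game))
  }
  fd <- function(size, role) {
    e <- 1e-6 * size
    (mutant_lw(size + e, role) - mutant_lw(size - e, role)) / (2 * e)
  }
  c(x = fd(x, "x"), y = fd(y, "y"))
}

#' Audit the Fisher condition at a strategy pair
#'
#' Reports the Fisher-condition gap `|p_x n_x - p_y n_y|` of the
#' fertilization-weighted fitness (zero to machine precision for every
#' model built under the [fertilization_model()] contract) alongside the
#' gap of the bare fitness `n * g * f`, which equals
#' `f * |n_x g_x - n_y g_y|` and is generally positive under anisogamy —
#' the seemingly paradoxical property of the bare model that the
#' fertilization term repairs.
#'
#' @inheritParams limited_log_fitness
#' @return A list with `gap_limited`, `gap_bare`, `p_x`, `p_y`, `F`.
#' @export
fisher_condition_audit <- function(x, y, game, model) {
  lf <- limited_log_fitness(x, y, game, model)
  n_x <- .gamete_number(x, game)
  n_y <- .gamete_number(y, game)
  f <- zygote_survival(x, y, game)
  bare_x <- n_x * gamete_survival(x, game) * f
  bare_y <- n_y * gamete_survival(y, game) * f
  list(gap_limited = lf$fisher_gap, gap_bare = abs(bare_x - bare_y),
       p_x = lf$p_x, p_y = lf$p_y, F = lf$F)
}
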