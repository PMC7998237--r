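# Report-building functions behind the command-line interface. Each
# returns a plain R object (list or data frame) that serializes cleanly
# to JSON or CSV.

.report_header <- function(game) {
  list(
    package_version = as.character(utils::packageVersion("gametegame")),
    config = list(M = game$M, alpha = game$alpha, beta = game$beta,
                  k = game$k, c = game$c, h = game$h, delta = game$delta,
                  gamete_survival_form = game$gamete_survival,
                  zygote_survival_form = game$zygote_survival)
  )
}

#' Solve report: closed form vs numerical oracle, with stability
#'
#' For one parameter set, computes the closed-form stable equilibrium
#' (exponential forms only), the numerical multistart root, the stability
#' record at the numerical root, the regime classification, and whether
#' the two routes agree within `tol_agree` (relative).
#'
#' @param game A [gamete_game()].
#' @param tol_agree Relative agreement tolerance between the closed-form
#'   and numerical equilibria.
#' @return A list of class `"solve_report"`; element `agreement_ok` is
#'   `NA` when no closed form exists for the selected survival forms.
#' @export
run_solve <- function(game, tol_agree = 1e-8) {
  stopifnot(inherits(game, "gamete_game"))
  rep <- .report_header(game)
  exponential <- game$gamete_survival == "exponential" &&
    game$zygote_survival == "exponential"
  num <- solve_equilibrium(game)
  num$stability <- stability_at(game, c(num$x, num$y))
  rep$numerical <- as.data.frame(num)
  rep$stability <- list(
    eigenvalues = Re(num$stability$eigenvalues),
    convergence_stable = num$stability$convergence_stable,
    globally_uninvadable = num$stability$globally_uninvadable,
    branching_flag = num$stability$branching_flag
  )
  cls <- classify_regime(game)
  rep$regime <- cls$regime
  rep$threshold <- list(parameter = cls$parameter, value = cls$threshold)
  if (exponential) {
    cf <- stable_equilibrium(game)
    rep$closed_form <- as.data.frame(cf)
    scale <- max(abs(c(cf$x, cf$y)))
    rep$agreement <- max(abs(sort(c(cf$x, cf$y)) -
                               sort(c(num$x, num$y)))) / scale
    rep$agreement_ok <- rep$agreement < tol_agree
  } else {
    rep$closed_form <- NULL
    rep$agreement <- NA_real_
    rep$agreement_ok <- NA
  }
  structure(rep, class = "solve_report")
}

#' @export
print.solve_report <- function(x, ...) {
  cat("Solve report (package", x$package_version, ")\n")
  cat("  regime:", x$regime, sprintf("(critical %s = %g)\n",
                                     x$threshold$parameter,
                                     x$threshold$value))
  cat(sprintf("  numerical equilibrium: x = %.8g, y = %.8g\n",
              x$numerical$x, x$numerical$y))
  if (!is.null(x$closed_form)) {
    cat(sprintf("  closed form:           x = %.8g, y = %.8g\n",
                x$closed_form$x, x$closed_form$y))
    cat(sprintf("  relative agreement %.3g (%s)\n", x$agreement,
                if (isTRUE(x$agreement_ok)) "OK" else "MISMATCH"))
  }
  cat(sprintf("  convergence stable: %s; globally uninvadable: %s\n",
              x$stability$convergence_stable,
              x$stability$globally_uninvadable))
  invisible(x)
}

#' Exact vs approximate gamete size-ratio curve
#'
#' Tabulates the exact and binomial-approximation macrogamete to
#' microgamete size ratios over a grid of `beta/alpha` values. The exact
#' curve rises continuously from 1 at the threshold `beta/alpha = 4`;
#' the approximate curve jumps discontinuously from 1 to 3 there — an
#' artefact of the approximation, not a model prediction. The ratio
#' depends only on `beta/alpha` (`k` and `M` cancel).
#'
#' @param beta_over_alpha Numeric grid of `beta/alpha` values (> 0).
#' @param alpha Gamete-survival scale used to realize the grid.
#' @return A data frame with columns `beta_over_alpha`, `exact`,
#'   `approximate`.
#' @examples
#' run_ratio_curve(c(2, 4, 8))
#' @export
run_ratio_curve <- function(beta_over_alpha, alpha = 1) {
  stopifnot(is.numeric(beta_over_alpha), length(beta_over_alpha) > 0,
            all(beta_over_alpha > 0), alpha > 0)
  rows <- lapply(beta_over_alpha, function(r) {
    g <- gamete_game(alpha = alpha, beta = r * alpha,
                     M = max(10, 2 * r * alpha))
    data.frame(beta_over_alpha = r,
               exact = size_ratio(g, "exact"),
               approximate = size_ratio(g, "approximate"))
  })
  do.call(rbind, rows)
}

#' Plot the exact vs approximate ratio curves
#'
#' Overlaid curves of the table from [run_ratio_curve()]: solid exact,
#' dashed approximate.
#'
#' @param curve Data frame from [run_ratio_curve()].
#' @param ... Passed to [graphics::plot()].
#' @return `curve`, invisibly.
#' @export
plot_ratio_curve <- function(curve, ...) {
  graphics::plot(curve$beta_over_alpha, curve$exact, type = "l",
                 xlab = expression(beta / alpha),
                 ylab = "macro:micro size ratio", ...)
  graphics::lines(curve$beta_over_alpha, curve$approximate, lty = 2)
  graphics::legend("topleft", c("exact", "approximate"), lty = c(1, 2),
                   bty = "n")
  invisible(curve)
}

#' Threshold-scan report
#'
#' Wraps [find_threshold()] and returns a serializable report with the
#' detected critical value and the bisection trace.
#'
#' @inheritParams find_threshold
#' @return A list of class `"scan_report"`.
#' @export
run_scan <- function(game, parameter, bracket, criterion, tol = 1e-6) {
  scan <- find_threshold(game, parameter, bracket, criterion, tol = tol)
  rep <- .report_header(game)
  rep$parameter <- scan$parameter
  rep$criterion <- scan$criterion
  rep$critical_value <- scan$critical_value
  rep$bracket <- scan$bracket
  rep$iterations <- scan$iterations
  rep$trace <- scan$trace
  structure(rep, class = "scan_report")
}

#' @export
print.scan_report <- function(x, ...) {
  cat(sprintf("Scan report: critical %s = %.8g (%s, %d bisections)\n",
              x$parameter, x$critical_value, x$criterion, x$iterations))
  invisible(x)
}

#' Gamete-limitation audit report
#'
#' Runs the Fisher-condition audit and both structure variants of the
#' gamete-limited selection gradient at a strategy pair.
#'
#' @inheritParams limited_log_fitness
#' @return A list of class `"limitation_report"`.
#' @export
run_limitation_audit <- function(x, y, game, model) {
  audit <- fisher_condition_audit(x, y, game, model)
  rep <- .report_header(game)
  rep$model <- model$name
  rep$point <- c(x = x, y = y)
  rep$p_x <- audit$p_x
  rep$p_y <- audit$p_y
  rep$F <- audit$F
  rep$fisher_gap_limited <- audit$gap_limited
  rep$fisher_gap_bare <- audit$gap_bare
  rep$gradient_panmictic <-
    limited_selection_gradient(x, y, game, model, "panmictic")
  rep$gradient_local_group <-
    limited_selection_gradient(x, y, game, model, "local_group")
  rep$gradient_base <- selection_gradient(x, y, game)
  structure(rep, class = "limitation_report")
}

#' @export
print.limitation_report <- function(x, ...) {
  cat(sprintf("Gamete-limitation audit at (x = %g, y = %g), model %s\n",
              x$point["x"], x$point["y"], x$model))
  cat(sprintf("  p_x = %.6g, p_y = %.6g, F = %.6g\n", x$p_x, x$p_y, x$F))
  cat(sprintf("  Fisher gap: %.3g (limited) vs %.6g (bare n*g*f)\n",
              x$fisher_gap_limited, x$fisher_gap_bare))
  invisible(x)
}
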