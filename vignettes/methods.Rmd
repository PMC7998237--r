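---
title: "Methods: the gamete-competition game and its numerical analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the gamete-competition game and its numerical analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gametegame)
```

## The model

Two self-incompatible mating types produce gametes of sizes $x$ and $y$ from
a fixed resource budget $M$. A parent investing size $x$ per gamete produces

$$n(x) = \left(\frac{M}{x}\right)^{1/k}, \qquad 0 < x \le M,$$

where $k \ge 1$ is the *trade-off exponent*: $k = 1$ is the exact
size–number trade-off $n = M/x$, while $k > 1$ makes gamete production
inefficient (doubling size costs less than half the numbers). The
constructor `division_tradeoff()` expresses the same family through a
per-division resource-retention fraction $q$, with $k = 1 - \log_2 q$.

Fitness multiplies three factors: gamete number, gamete survival $g$, and
the survival $f$ of the zygote formed with a partner gamete of size $y$,

$$w(x, y) = n(x)\, g(x)\, f(x + y).$$

Two survival families are implemented:

* **exponential**: $g(x) = e^{-\alpha / x}$ and
  $f(s) = c\, e^{-\beta / s}$, with $\alpha$ the gamete-survival scale and
  $\beta$ the zygote-survival scale (both in units of gamete size);
* **threshold/power**: $g(x) = \mathbf{1}[x \ge \delta]$ (gametes below a
  minimum viable size $\delta$ are dead; `log_fitness()` returns `-Inf`
  there) and $f(s) = c\, s^{h}$ with exponent $h > 0$.

The selection gradient on the focal type's (log) fitness is available in
closed form (`selection_gradient()`, `gradient_jacobian()`); for the
exponential family

$$\frac{\partial \ln w}{\partial x}
  = -\frac{1}{kx} + \frac{\alpha}{x^2} + \frac{\beta}{(x+y)^2}.$$

### Defaults and units

All sizes ($x$, $y$, $M$, $\alpha$, $\beta$, $\delta$) share one arbitrary
size unit; $k$, $h$, $c$ are dimensionless. `gamete_game()` defaults:
$M = 10$, $\alpha = 1$, $\beta = 2$, $k = 1$, $c = 1$, $h = 1$,
$\delta = 10^{-3}$, exponential survival forms.

## Closed-form equilibria (exponential family)

Setting both partial gradients to zero gives, for $k \ge 1$,

* an **isogamous** solution $x = y = k(\alpha + \beta/4)$
  (`isogamous_equilibrium()`), always present;
* an **anisogamous** pair on the constraint line $x + y = k\beta$,
  $$x^{*} = \frac{k\beta}{2}\left(1 + \sqrt{1 - 4\alpha/\beta}\right),
    \qquad y^{*} = k\beta - x^{*},$$
  real only when $\beta > 4\alpha$ (`anisogamous_equilibrium()`; a
  `no_anisogamy` marker object is returned otherwise).

The isogamous point is convergence stable for $\beta < 4\alpha$ and a
saddle for $\beta > 4\alpha$: the Jacobian eigenvalues there are
$-(\alpha + \beta/4)/m^3$ and $(\beta/4 - \alpha)/m^3$ with
$m = k(\alpha + \beta/4)$ (up to the $k$ scaling), so the leading
eigenvalue changes sign exactly at $\beta = 4\alpha$, independent of $k$.
`stable_equilibrium()` returns the piecewise-stable branch; it is
continuous at the threshold (both branches equal $x = y = 2k\alpha$).

When gamete survival is neglected in the zygote term (a binomial
approximation valid for $\beta \gg \alpha$), the equilibrium simplifies to
$x \approx k(\beta - \alpha)$, $y \approx k\alpha$
(`approximate_equilibrium()`). Its size ratio $\beta/\alpha - 1$ jumps
from $1$ to $3$ at the $\beta = 4\alpha$ onset — an artefact of the
approximation, since the exact ratio $(1+s)/(1-s)$,
$s = \sqrt{1 - 4\alpha/\beta}$, rises continuously from $1$. The package
keeps both: `size_ratio(game, method = c("exact", "approximate"))`.
Tie convention: at exactly $\beta = 4\alpha$ the exact method reports $1$
(the branches coincide), while the approximate method reports the onset
value $\beta/\alpha - 1 = 3$, matching how the approximation is used in
threshold scans.

## Numerical methods

**Root finding** (`solve_equilibrium()`): damped Newton iteration on the
gradient system using the closed-form Jacobian, with step halving until
the residual decreases and coordinates clamped above the domain floor.
When no explicit start is given, a multistart set is used — the isogamous
point $(m, m)$, two near-corner starts $(0.9M, 2\delta)$ and its mirror,
and (for exponential forms with $\beta > 4\alpha$) the binomial
approximation $(k(\beta-\alpha), k\alpha)$ and its mirror, which is
essential at large parameter scales where the corner starts stall. Among
converged roots the convergence-stable one is preferred, macrogamete
first. `converged` requires gradient residual below `tol` ($10^{-10}$
default); after convergence the iteration polishes toward
$\min(\texttt{tol}, 10^{-15})$ so positions are accurate to near machine
precision, not merely to the residual tolerance.

**Stability** (`stability_at()`): requires a gradient residual below
$10^{-8}$ at the supplied point, then reports (i) convergence stability
via the Jacobian eigenvalues (sorted descending) and (ii) global
uninvadability by scanning mutant invasion gains for both roles over a
log-spaced grid of 400 mutant sizes on $[\delta, M]$, plus a branching
flag.

**Threshold detection** (`find_threshold()`): bisection to a parameter
tolerance of $10^{-6}$ (default) with a full trace. Two criteria:

* `isogamy_destabilised` — sign of the leading Jacobian eigenvalue at the
  closed-form isogamous point (parameter `beta`); deterministic, no grid.
  The result is invariant to evaluating the Jacobian on the log- or
  absolute-fitness scale, since positive scaling by $\mathrm{diag}(w)$
  cannot change the sign of the leading eigenvalue at a gradient zero.
* `boundary_invadable` — whether any grid mutant invades the minimal-size
  isogamous resident $(\delta, \delta)$ (parameter `h`).

**Finite-$\delta$ bias and extrapolation**
(`asymptotic_h_threshold()`): in the threshold/power model the condition
for anisogamy, $hk > 1$, holds in the limit $\delta/M \to 0$. At any
finite $\delta$ the boundary-invasibility criterion instead detects

$$h_\mathrm{crit}(\delta)
  = \frac{\ln(M/\delta)}{k \, \ln\!\big((M+\delta)/(2\delta)\big)},$$

the value at which the extreme mutant $x = M$ breaks even against the
$(\delta, \delta)$ resident — about $1.11/k$ at $\delta = 10^{-3}$,
$M = 1$. This was derived analytically before implementation and is
asserted, as a closed form, in the test suite. Because the bias is a
smooth function of $u = 1/\ln(M/\delta)$ with $h_\mathrm{crit} \to 1/k$
as $u \to 0$, `asymptotic_h_threshold()` runs the bisection at
$\delta \in \{10^{-6}, 10^{-9}, 10^{-12}\}$ and extrapolates a polynomial
in $u$ to $u = 0$. With the default 400-point mutant grid this recovers
$h_\mathrm{crit} k = 1$ to about $5 \times 10^{-5}$.

**Adaptive dynamics** (`evolve_trajectory()`): explicit Euler steps along
the two-type selection gradient, clamped to the feasible box ($[\delta, M]$
under the threshold form). Default step size $0.01\min(\alpha, \beta)$ for
exponential forms, $0.01 M$ otherwise. Convergence uses the projected
gradient: coordinates pinned at a boundary with an outward gradient
contribute zero, so boundary equilibria such as $(M, \delta)$ are
recognised. Trajectories started exactly on the diagonal stay on it by
symmetry — the implementation preserves this identically in floating
point.

## Gamete limitation

A `fertilization_model()` supplies a symmetric count function
$F(n_x, n_y) \le \min(n_x, n_y)$ for the number of zygotes formed.
Per-gamete fertilization probabilities are constructed as $p_x = F/n_x$,
$p_y = F/n_y$, so the Fisher condition $p_x n_x = p_y n_y$ holds *by
construction*, to machine precision, for any admissible model — built-ins
are `complete_fertilization()` ($F = \min$) and
`saturating_fertilization(s)` ($F = n_x n_y/(n_x + n_y + s)$). Contract
violations (excess counts, asymmetry) are rejected at evaluation time.

Under **panmictic** population structure the focal mutant's probability is
evaluated at the resident gamete pool, so the limited selection gradient
equals the bare gradient pointwise and every equilibrium of the base game
survives arbitrary gamete scarcity unchanged. Under **local_group**
structure (one mating pair) the mutant's own output moves $F$, and the
gradient genuinely differs. Limited gradients are computed by central
finite differences with a relative step of $10^{-6}$, since $F$ is
user-pluggable and need not be differentiable in closed form.

## Reporting

`run_solve()`, `run_scan()`, `run_ratio_curve()` and
`run_limitation_audit()` bundle the numerical result, the closed-form
cross-check, the stability record, the regime classification, the full
resolved configuration and the package version into classed,
JSON-serializable report objects. The installed command-line interface
(`system.file("cli", "gamete_game.R", package = "gametegame")`) exposes
the same pipelines (`solve`, `scan`, `trajectory`, `ratio-curve`,
`limitation-audit`) with JSON/CSV output, config files via
`read_game_config()` with flag overrides, logs on stderr, and a nonzero
exit status when the numerical and closed-form answers disagree.

## Problem sizes and limitations

Default scans use 400 mutant grid points and bisection to $10^{-6}$;
trajectory integration caps at $2 \times 10^5$ Euler steps. All routines
are deterministic. Known limitations: the closed forms cover only the
exponential family; the boundary-invasibility criterion inherits the
finite-$\delta$ bias described above (use `asymptotic_h_threshold()` for
the limit value); `limited_selection_gradient()` uses finite differences
and so carries $O(10^{-6})$ truncation error; explicit Euler is first
order, adequate here because only the attractor, not the transient, is of
interest.
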