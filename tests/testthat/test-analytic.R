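test_that("isogamous equilibrium is k * (alpha + beta/4)", {
  eq <- isogamous_equilibrium(iso_game())
  expect_equal(c(eq$x, eq$y), c(1.5, 1.5))
  expect_identical(eq$regime, "isogamy")
  eq3 <- isogamous_equilibrium(iso_game(k = 3))
  expect_equal(c(eq3$x, eq3$y), c(4.5, 4.5))
  # coincides with the anisogamous branch at the threshold beta = 4 alpha
  g4 <- gamete_game(alpha = 1, beta = 4, M = 10)
  expect_equal(isogamous_equilibrium(g4)$x, 2)
  expect_error(isogamous_equilibrium(power_game()), "exponential")
})

test_that("anisogamous equilibrium matches the quadratic roots", {
  eq <- anisogamous_equilibrium(aniso_game())
  expect_equal(c(eq$x, eq$y), c(4 * (1 + sqrt(0.5)), 4 * (1 - sqrt(0.5))),
               tolerance = 1e-12)
  # independently root-found values
  expect_equal(c(eq$x, eq$y), c(6.828427, 1.171573), tolerance = 1e-6)
  expect_gte(eq$x, eq$y) # macrogamete-first convention
  # k scales both sizes linearly
  eq2 <- anisogamous_equilibrium(aniso_game(k = 2))
  expect_equal(c(eq2$x, eq2$y), 2 * c(eq$x, eq$y), tolerance = 1e-12)
  # no real asymmetric solution at or below the threshold
  expect_s3_class(anisogamous_equilibrium(iso_game()), "no_anisogamy")
  expect_s3_class(anisogamous_equilibrium(gamete_game(alpha = 1, beta = 4)),
                  "no_anisogamy")
})

test_that("anisogamous sizes satisfy the sum constraint x + y = k * beta", {
  for (k in c(1, 1.5, 3)) {
    for (r in seq(4.1, 60, length.out = 12)) {
      g <- gamete_game(alpha = 0.7, beta = 0.7 * r, k = k,
                       M = 2 * 0.7 * r * k)
      eq <- anisogamous_equilibrium(g)
      expect_equal(eq$x + eq$y, k * g$beta, tolerance = 1e-12)
    }
  }
})

test_that("the stable equilibrium is piecewise and continuous at onset", {
  expect_equal(stable_equilibrium(gamete_game(alpha = 1, beta = 3.9))$x,
               1.975)
  expect_identical(stable_equilibrium(aniso_game())$regime, "anisogamy")
  # both branches tend to 2 * k * alpha at beta = 4 * alpha
  for (k in c(1, 2)) {
    for (eps in 10^seq(-3, -9, by = -2)) {
      lo <- stable_equilibrium(gamete_game(alpha = 1, beta = 4 - eps, k = k))
      hi <- stable_equilibrium(gamete_game(alpha = 1, beta = 4 + eps, k = k))
      gap <- max(abs(c(lo$x - hi$x, lo$y - hi$y)))
      expect_lt(gap, 3 * k * sqrt(eps)) # square-root onset of the split
    }
    eps <- 1e-12
    lo <- stable_equilibrium(gamete_game(alpha = 1, beta = 4 - eps, k = k))
    hi <- stable_equilibrium(gamete_game(alpha = 1, beta = 4 + eps, k = k))
    expect_equal(c(lo$x, lo$y, hi$x, hi$y), rep(2 * k, 4), tolerance = 1e-5)
  }
})

test_that("the binomial approximation is good far from onset, poor near it", {
  eq <- approximate_equilibrium(aniso_game())
  expect_equal(c(eq$x, eq$y), c(7, 1))
  expect_identical(eq$source, "approximation")
  # beta/alpha = 100: approximation close to the exact solution
  g100 <- gamete_game(alpha = 1, beta = 100, M = 300)
  ap <- approximate_equilibrium(g100)
  ex <- anisogamous_equilibrium(g100)
  expect_equal(c(ex$x, ex$y), c(98.9898, 1.0102), tolerance = 1e-4)
  expect_lt(abs(ap$y - ex$y) / ex$y, 0.02)
  # near onset (beta/alpha = 4.4) the approximation is grossly wrong
  g44 <- gamete_game(alpha = 1, beta = 4.4)
  ap <- approximate_equilibrium(g44)
  ex <- anisogamous_equilibrium(g44)
  expect_equal(c(ex$x, ex$y), c(2.8633, 1.5367), tolerance = 1e-4)
  expect_equal(c(ap$x, ap$y), c(3.4, 1))
  expect_gt(abs(ap$y - ex$y) / ex$y, 0.3)
  expect_s3_class(approximate_equilibrium(iso_game()), "no_anisogamy")
})

test_that("exact size ratio is continuous, increasing and k/M invariant", {
  expect_equal(size_ratio(gamete_game(alpha = 1, beta = 4)), 1)
  expect_equal(size_ratio(aniso_game()), 3 + 2 * sqrt(2), tolerance = 1e-12)
  expect_equal(size_ratio(aniso_game(), "approximate"), 7)
  # depends only on beta/alpha: k and M cancel
  base <- size_ratio(gamete_game(alpha = 0.5, beta = 4.5, M = 20))
  for (k in c(1, 1.5, 3)) {
    for (M in c(15, 40)) {
      expect_identical(size_ratio(gamete_game(alpha = 0.5, beta = 4.5,
                                              k = k, M = M)), base)
    }
  }
  # strictly increasing in beta/alpha above onset, unbounded
  rr <- vapply(seq(4.01, 400, length.out = 40), function(r) {
    size_ratio(gamete_game(alpha = 1, beta = r, M = 2 * r))
  }, numeric(1))
  expect_true(all(diff(rr) > 0))
  expect_gt(max(rr), 100)
})

test_that("exact microgamete size converges to k * alpha as beta/alpha grows", {
  for (k in c(1, 2)) {
    g <- gamete_game(alpha = 1, beta = 100, k = k, M = 300)
    micro <- anisogamous_equilibrium(g)$y
    expect_lt(abs(micro - k * 1) / (k * 1), 0.02)
  }
  # relative error shrinks monotonically with beta/alpha
  errs <- vapply(c(10, 30, 100, 300), function(r) {
    g <- gamete_game(alpha = 1, beta = r, M = 3 * r)
    abs(anisogamous_equilibrium(g)$y - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("regime classification reports the analytic threshold", {
  expect_identical(classify_regime(gamete_game(alpha = 1, beta = 3.99))$regime,
                   "isogamy")
  expect_identical(classify_regime(gamete_game(alpha = 1, beta = 4.01))$regime,
                   "anisogamy")
  cls <- classify_regime(gamete_game(alpha = 2, beta = 1, k = 3))
  expect_identical(cls$threshold, 8) # beta_crit = 4 alpha, k-independent
  # ties are isogamy
  expect_identical(classify_regime(gamete_game(alpha = 1, beta = 4))$regime,
                   "isogamy")
  # power-law variant: anisogamy iff h * k > 1
  expect_identical(classify_regime(power_game(h = 0.9, k = 1))$regime,
                   "isogamy")
  expect_identical(classify_regime(power_game(h = 1.1, k = 1))$regime,
                   "anisogamy")
  cls <- classify_regime(power_game(h = 0.6, k = 2))
  expect_identical(cls$regime, "anisogamy") # h*k = 1.2 > 1
  expect_identical(cls$threshold, 0.5)
})

test_that("equilibria export to flat data frame rows", {
  df <- as.data.frame(stable_equilibrium(aniso_game(k = 2)))
  expect_identical(names(df), c("alpha", "beta", "k", "regime", "x", "y",
                                "ratio", "source"))
  expect_identical(df$regime, "anisogamy")
  expect_equal(df$ratio, 3 + 2 * sqrt(2), tolerance = 1e-12)
})
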