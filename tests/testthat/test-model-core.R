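test_that("parameter validation rejects out-of-domain values by name", {
  expect_error(gamete_game(M = -1), "M")
  expect_error(gamete_game(k = 0.5), "k")
  expect_error(gamete_game(delta = 0), "delta")
  expect_error(gamete_game(M = 1, delta = 2), "delta")
  expect_error(gamete_game(h = 0), "h")
  expect_error(gamete_game(c = -1), "c")
})

test_that("gamete number follows the size-number trade-off", {
  expect_equal(gamete_number(1, gamete_game(M = 100, k = 1)), 100)
  expect_equal(gamete_number(4, gamete_game(M = 100, k = 2)), 5)
  # whole budget in a single gamete, any k
  for (k in c(1, 1.7, 3)) {
    expect_equal(gamete_number(100, gamete_game(M = 100, k = k)), 1)
  }
  # strictly decreasing in size
  g <- gamete_game(M = 100, k = 2.5)
  n <- gamete_number(seq(0.1, 100, length.out = 50), g)
  expect_true(all(diff(n) < 0))
  expect_error(gamete_number(0, g), "> 0")
  expect_error(gamete_number(101, g), "<= M")
})

test_that("cell-division reparametrisation is consistent and round-trips", {
  r <- division_tradeoff(k = 1, d = 3, M = 8)
  expect_equal(c(r$q, r$n, r$x), c(1, 8, 1))
  r <- division_tradeoff(k = 2, d = 1, M = 8)
  expect_equal(c(r$q, r$n, r$x), c(0.5, 2, 2))
  r <- division_tradeoff(k = 2, d = 2, M = 8)
  expect_equal(c(r$q, r$n, r$x), c(0.5, 4, 0.5))
  # x agrees with M / n^k directly
  expect_equal(r$x, 8 / r$n^2)
  # k -> q -> k identity to machine precision; q = 1 iff k = 1
  for (k in c(1, 1.25, 2, 3.5, 7)) {
    r <- division_tradeoff(k, d = 4, M = 5)
    expect_equal(r$k, k, tolerance = 1e-14)
    expect_identical(r$q == 1, k == 1)
  }
  expect_error(division_tradeoff(0.9, 1, 1), ">= 1")
  expect_error(division_tradeoff(2, 1.5, 1), "integer")
})

test_that("survival components match their functional forms", {
  g <- gamete_game(alpha = 2, beta = 3, M = 10)
  expect_equal(gamete_survival(2, g), exp(-1))
  expect_equal(gamete_survival(5, update_game(g, alpha = 0)), 1)
  expect_equal(zygote_survival(1, 2, g), exp(-1))
  expect_equal(zygote_survival(1, 2, update_game(g, beta = 0)), 1)
  # threshold step at delta
  gt <- update_game(g, gamete_survival = "threshold", delta = 0.5)
  expect_equal(gamete_survival(0.5 * 0.99, gt), 0)
  expect_equal(gamete_survival(0.5, gt), 1)
  # power-law zygote survival is a fitness factor, not capped at 1
  gp <- update_game(g, zygote_survival = "power", c = 1, h = 1)
  expect_equal(zygote_survival(1.2, 0.8, gp), 2)
  expect_error(gamete_survival(-1, g), "> 0")
  expect_error(zygote_survival(0, 1, g), "> 0")
})

test_that("log fitness composes the three components and is role symmetric", {
  g <- gamete_game(M = 1, alpha = 1, beta = 2, k = 1, delta = 1e-4)
  expect_equal(log_fitness(1.5, 1.5, g), -1.7387985, tolerance = 1e-7)
  # dual route: composition of the component functions
  comp <- log(gamete_number(0.8, g) * gamete_survival(0.8, g) *
                zygote_survival(0.8, 0.6, g))
  expect_equal(log_fitness(0.8, 0.6, g), comp, tolerance = 1e-12)
  # doubling M raises log fitness by exactly log(2)/k
  for (k in c(1, 3)) {
    gk <- update_game(g, k = k, M = 2)
    g2 <- update_game(gk, M = 4)
    expect_equal(log_fitness(0.7, 0.9, g2) - log_fitness(0.7, 0.9, gk),
                 log(2) / k, tolerance = 1e-12)
  }
  # the same function serves both mating types with arguments swapped:
  # the y-gradient at (a, b) is the x-gradient at (b, a)
  set.seed(7)
  pts <- matrix(runif(20, 0.2, 5), ncol = 2)
  gi <- gamete_game(M = 10, alpha = 0.6, beta = 3, k = 1.5)
  for (i in seq_len(nrow(pts))) {
    a <- pts[i, 1]; b <- pts[i, 2]
    gr <- selection_gradient(a, b, gi)
    gr_swap <- selection_gradient(b, a, gi)
    expect_identical(unname(gr["x"]), unname(gr_swap["y"]))
    expect_identical(unname(gr["y"]), unname(gr_swap["x"]))
  }
  # inviable-gamete sentinel is -Inf, distinct from the domain error
  gt <- power_game(h = 1.5, delta = 1e-2)
  expect_identical(log_fitness(5e-3, 0.5, gt), -Inf)
  expect_error(log_fitness(-1, 0.5, gt), "> 0")
})

test_that("closed-form selection gradients match a finite-difference oracle", {
  games <- list(
    gamete_game(M = 10, alpha = 1, beta = 2, k = 1),
    gamete_game(M = 10, alpha = 0.3, beta = 6, k = 2.5),
    gamete_game(M = 5, alpha = 2, beta = 1, k = 1.5,
                zygote_survival = "power", c = 0.7, h = 1.8),
    power_game(h = 1.4, k = 1, delta = 1e-3),
    power_game(h = 0.8, k = 2, delta = 1e-3)
  )
  pts <- list(c(0.5, 0.8), c(1.5, 1.5), c(3, 0.2), c(0.05, 0.9))
  for (g in games) {
    for (p in pts) {
      if (g$gamete_survival == "threshold" &&
          any(p - 1e-6 * pmax(1, p) < g$delta)) next
      expect_equal(selection_gradient(p[1], p[2], g),
                   fd_gradient(p[1], p[2], g), tolerance = 1e-5)
    }
  }
})

test_that("gradients vanish at analytic equilibria under both conventions", {
  expect_equal(selection_gradient(1.5, 1.5, iso_game()),
               c(x = 0, y = 0), tolerance = 1e-12)
  # anisogamous root of the gradient system (independently root-found)
  expect_lt(max(abs(selection_gradient(6.828427, 1.171573, aniso_game()))),
            1e-6)
  for (g in list(iso_game(), aniso_game(), aniso_game(k = 2.5))) {
    eq <- stable_equilibrium(g)
    for (type in c("log", "absolute")) {
      expect_lt(max(abs(selection_gradient(eq$x, eq$y, g, type = type))),
                1e-8)
    }
  }
})

test_that("the k-scaled game obeys the bracket identity", {
  # gradient of the (alpha*k, beta*k) game at k = 1 is exactly k times
  # the gradient of the k-game at (alpha, beta)
  pts <- list(c(0.7, 1.3), c(2, 2), c(4, 0.5))
  for (k in c(1.5, 3)) {
    gk <- gamete_game(M = 10, alpha = 0.8, beta = 5, k = k)
    g1 <- gamete_game(M = 10, alpha = 0.8 * k, beta = 5 * k, k = 1)
    for (p in pts) {
      expect_equal(selection_gradient(p[1], p[2], g1),
                   k * selection_gradient(p[1], p[2], gk),
                   tolerance = 1e-12)
    }
  }
})

test_that("power-law diagonal gradient equals (h - 2) / (2m) when k = 1", {
  for (h in c(0.8, 1.5, 2.5)) {
    g <- power_game(h = h, k = 1, delta = 1e-3)
    for (m in c(0.01, 0.1, 0.4)) {
      expect_equal(selection_gradient(m, m, g),
                   c(x = (h - 2) / (2 * m), y = (h - 2) / (2 * m)),
                   tolerance = 1e-12)
    }
  }
})

test_that("survival and trade-off components are monotone", {
  g <- gamete_game(M = 10, alpha = 1.3, beta = 4)
  x <- seq(0.05, 9, length.out = 60)
  expect_true(all(diff(gamete_survival(x, g)) > 0))
  expect_true(all(diff(zygote_survival(x, 0.5, g)) > 0))
  gp <- update_game(g, zygote_survival = "power", h = 2)
  expect_true(all(diff(zygote_survival(x, 0.5, gp)) > 0))
})

test_that("the gradient-system Jacobian matches a finite-difference oracle", {
  for (g in list(iso_game(), aniso_game(k = 2),
                 power_game(h = 1.3, delta = 1e-3))) {
    p <- if (g$gamete_survival == "threshold") c(0.2, 0.05) else c(2.5, 1.1)
    expect_equal(gradient_jacobian(p[1], p[2], g),
                 fd_jacobian(p[1], p[2], g), tolerance = 1e-4,
                 ignore_attr = TRUE)
  }
})

test_that("game configurations round-trip through flat JSON", {
  g <- gamete_game(M = 3, alpha = 0.2, beta = 1.7, k = 2.25, c = 0.9,
                   h = 1.1, delta = 1e-4, gamete_survival = "threshold",
                   zygote_survival = "power")
  path <- tempfile(fileext = ".json")
  write_game_config(g, path)
  keys <- names(jsonlite::read_json(path))
  expect_identical(keys, c("M", "alpha", "beta", "k", "c", "h", "delta",
                           "gamete_survival_form", "zygote_survival_form"))
  expect_identical(read_game_config(path), g)
})
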