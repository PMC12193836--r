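test_that("weight factor matches the arctan closed form and decays", {
  ctrl <- lgwo_control()
  # t = 0, Tmax = 30: arctan(1) = pi/4 -> bracket 0.8; (28/30) * 0.64
  expect_equal(weight_factor(0, 30, ctrl), 0.8^2 * 28 / 30, tolerance = 1e-12)
  expect_equal(weight_factor(0, 30, ctrl), 0.5973333, tolerance = 1e-6)
  # t -> infinity: bracket -> we, so O -> (Tmax-2)/Tmax * we^2
  expect_equal(weight_factor(1e12, 30, ctrl), 28 / 30 * 0.01,
               tolerance = 1e-6)
  O <- vapply(seq(0, 2000, by = 10), weight_factor, numeric(1), Tmax = 500,
              control = ctrl)
  expect_true(all(diff(O) < 0))
})

test_that("escape-move algebra matches the defining formulas", {
  expect_equal(greedy_levy_update(1, 0, 0.5, 2), 2)        # 1 + 0.5*2*1
  expect_equal(greedy_levy_update(c(3, 3), c(3, 3), 0.7, 5), c(3, 3))
  expect_equal(greedy_levy_update(c(1, 2), c(0, 1), 1, 0), c(1, 2))

  expect_equal(opposition(c(0.3, -0.8), -1, 1, 1), -c(0.3, -0.8))
  expect_equal(opposition(0.25, 0, 1, 1), 0.75)
  expect_equal(opposition(c(9, 9), 0, 1, 0), c(1, 1))

  x <- c(2, -1); xb <- c(0.5, 0.5)
  expect_equal(drift_update(x, xb, 1), xb)
  expect_equal(drift_update(x, xb, 0), x)
  expect_equal(drift_update(xb, xb, 3.7), xb)

  expect_equal(contraction_update(c(2, -4), 0.5), c(1, -2))
  expect_equal(contraction_update(c(2, -4), 1), c(2, -4))
  expect_equal(contraction_update(c(2, -4), 0), c(0, 0))
})

test_that("mutation candidates reduce correctly under forced draws", {
  zero <- list(r1 = rep(0, 2), r2 = rep(0, 2), r3 = rep(0, 2),
               r4 = rep(0, 2))
  m <- hho_mutation(c(1, 1), c(4, 5), c(0.5, 0.5), c(2, 2), -5, 5,
                    rand = zero)
  expect_equal(m$x3, c(4, 5))            # rand = 0: x3 = x_r
  expect_equal(m$x4, c(-1.5, -1.5))      # rand = 0: x4 = x_best - x_mean

  half <- list(r1 = 0.5, r2 = 0.5, r3 = 0.5, r4 = 0.5)
  m <- hho_mutation(1, 2, 0, 0, -5, 5, rand = half)
  expect_equal(m$x3, 2 - 0.5 * abs(2 - 2 * 0.5 * 1))   # = 1.5
})

test_that("Levy repositioning scales with the leader offset", {
  ctrl <- lgwo_control()
  expect_equal(levy_restart(c(1, 1), c(1, 1), ctrl), c(0, 0))
  set.seed(31); s1 <- levy_restart(c(2, 0), c(0, 0), ctrl)
  set.seed(31); s2 <- levy_restart(c(4, 0), c(0, 0), ctrl)
  expect_equal(s2, 2 * s1)
})

test_that("with mutation and escapes disabled LGWO reduces to GWO bitwise", {
  for (id in c("f1", "f9")) {
    fb <- get_benchmark(id)
    for (seed in 1:3) {
      a <- lgwo_optimize(fb$fnm, 10, fb$lower, fb$upper,
                         lgwo_control(10, 40, pp = 0,
                                      stagnation_window = 1000L),
                         seed = seed, vectorized = TRUE)
      b <- gwo_optimize(fb$fnm, 10, fb$lower, fb$upper,
                        gwo_control(10, 40), seed = seed, vectorized = TRUE)
      expect_identical(a$curve, b$curve)
      expect_identical(a$best_position, b$best_position)
      expect_identical(a$n_evals, b$n_evals)
    }
  }
})

test_that("greedy acceptance keeps the convergence curve monotone", {
  for (id in c("f8", "f12")) {
    fb <- get_benchmark(id)
    r <- lgwo_optimize(fb$fnm, fb$dim, fb$lower, fb$upper,
                       lgwo_control(15, 80), seed = 6, vectorized = TRUE)
    expect_true(all(diff(r$curve) <= 0))
    expect_true(all(abs(r$best_position) <= fb$upper))
  }
})

test_that("the full protocol collapses the 30-d sphere to exactly zero", {
  fb <- get_benchmark("f1")
  r <- lgwo_optimize(fb$fnm, fb$dim, fb$lower, fb$upper,
                     lgwo_control(30, 500), seed = 1, vectorized = TRUE)
  expect_identical(r$best_fitness, 0)
})

test_that("control validation rejects inconsistent parameters", {
  expect_error(lgwo_control(ws = 0.1, we = 1.5))
  expect_error(lgwo_control(pp = 1.5))
  expect_error(lgwo_control(beta_levy = 2))
  expect_error(gwo_control(n_agents = 2))
})
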