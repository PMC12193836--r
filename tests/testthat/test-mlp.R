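test_that("parameter counts follow h*i + h + o*h + o", {
  expect_equal(n_params(1, 1, 1), 4L)
  expect_equal(n_params(16, 6, 1), 109L)
  expect_equal(n_params(30, 6, 1), 193L)
  expect_equal(mlp_shape(16)$n_params, 109L)
})

test_that("sigmoid is exact, symmetric and overflow-safe", {
  expect_equal(sigmoid(0), 0.5)
  x <- c(-3, -0.5, 0.2, 4)
  expect_equal(sigmoid(-x), 1 - sigmoid(x))
  expect_identical(sigmoid(700), 1)
  expect_equal(sigmoid(-700), 9.86e-305, tolerance = 1e-2)
  expect_true(all(is.finite(sigmoid(c(-1e6, 1e6)))))
})

test_that("encode/decode round trip is exact", {
  shape <- mlp_shape(7, 4, 2)
  set.seed(14)
  p <- rnorm(shape$n_params)
  expect_identical(levywolf:::.encode_params(levywolf:::.decode_params(p, shape)), p)
})

test_that("forward pass matches hand computation", {
  shape <- mlp_shape(3, 6, 1)
  X <- matrix(rnorm(15), 5, 3)
  expect_equal(as.vector(mlp_forward(rep(0, shape$n_params), shape, X)),
               rep(0.5, 5))

  s111 <- mlp_shape(1, 1, 1)
  # v = 1, theta_v = 0, w = 1, theta_w = 0, x = 0 -> sigmoid(sigmoid(0))
  out <- mlp_forward(c(1, 0, 1, 0), s111, matrix(0, 1, 1))
  expect_equal(out[1, 1], sigmoid(0.5))
  expect_equal(out[1, 1], 0.6224593, tolerance = 1e-6)

  set.seed(15)
  big <- mlp_forward(rnorm(shape$n_params, sd = 5), shape, X * 100)
  expect_true(all(big > 0 & big < 1))
  expect_error(mlp_forward(rep(0, shape$n_params), shape, matrix(0, 2, 4)),
               "columns")
})

test_that("fitness is the MSE against 0/1 labels", {
  shape <- mlp_shape(4, 6, 1)
  set.seed(16)
  X <- matrix(runif(40), 10, 4)
  y <- rbinom(10, 1, 0.5)
  expect_equal(mlp_fitness(rep(0, shape$n_params), shape, X, y), 0.25)
  p <- rnorm(shape$n_params)
  expect_equal(mlp_fitness(p, shape, X, y),
               mean((mlp_forward(p, shape, X) - y)^2))
  # invariant under sample permutation
  idx <- sample(10)
  expect_equal(mlp_fitness(p, shape, X[idx, ], y[idx]),
               mlp_fitness(p, shape, X, y))
  expect_error(mlp_fitness(p, shape, X[0, , drop = FALSE], y[0]), "empty")
})

test_that("analytic gradient matches central finite differences", {
  shape <- mlp_shape(3, 2, 1)
  for (seed in 1:3) {
    d <- random_labeled(12, 3, seed)
    p <- rnorm(shape$n_params, sd = 0.5)
    g <- levywolf:::.mlp_grad(p, shape, d$X, d$y)
    fd <- fd_gradient(p, shape, d$X, d$y)
    expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-6)
  }
})

test_that("refinement honours its no-op cases and descends at small rates", {
  shape <- mlp_shape(5, 6, 1)
  d <- random_labeled(30, 5, 20)
  p <- rnorm(shape$n_params, sd = 0.3)
  expect_identical(bp_refine(p, shape, d$X, d$y, lr = 0), p)
  expect_identical(bp_refine(p, shape, d$X, d$y, epochs = 0), p)
  for (seed in 1:20) {
    set.seed(seed)
    p0 <- runif(shape$n_params, -1, 1)
    p1 <- bp_refine(p0, shape, d$X, d$y, lr = 1e-3, epochs = 10)
    expect_lte(mlp_fitness(p1, shape, d$X, d$y),
               mlp_fitness(p0, shape, d$X, d$y) + 1e-12)
  }
})

test_that("gradient descent makes progress on the separable fixture", {
  d <- sim_fixtures()$separable
  X <- as.matrix(d[, 1:5])
  X <- sweep(sweep(X, 2, apply(X, 2, min)), 2,
             apply(X, 2, max) - apply(X, 2, min), `/`)
  shape <- mlp_shape(5, 6, 1)
  p0 <- rep(0, shape$n_params)
  p1 <- bp_refine(p0, shape, X, d$label, lr = 0.5, epochs = 200)
  expect_lt(mlp_fitness(p1, shape, X, d$label),
            mlp_fitness(p0, shape, X, d$label))
})

test_that("thresholding is monotone with the documented tie rule", {
  shape <- mlp_shape(2, 3, 1)
  set.seed(17)
  X <- matrix(rnorm(20), 10, 2)
  p <- rnorm(shape$n_params)
  expect_equal(mlp_predict(rep(0, shape$n_params), shape, X),
               rep(1L, 10))           # outputs exactly 0.5, >= rule
  expect_equal(mlp_predict(p, shape, X, threshold = 1), rep(0L, 10))
  lo <- mlp_predict(p, shape, X, threshold = 0.3)
  hi <- mlp_predict(p, shape, X, threshold = 0.7)
  expect_true(all(hi <= lo))
})

test_that("the hybrid fit learns, is deterministic, and exposes methods", {
  d <- sim_fixtures()$separable
  fit <- lgwo_nnet(label ~ ., d, seed = 1)
  expect_s3_class(fit, "lgwo_nnet")
  expect_gte(mean(predict(fit, d) == d$label), 0.95)

  fit2 <- lgwo_nnet(label ~ ., d, seed = 1)
  expect_identical(fit$params, fit2$params)

  raw <- lgwo_nnet(label ~ ., d, seed = 3, epochs = 0)
  expect_identical(raw$params, raw$opt$best_position)

  p <- predict(fit, d, type = "prob")
  expect_true(all(p > 0 & p < 1))
  expect_length(residuals(fit), nrow(d))
  expect_named(coef(fit), c("input_weights", "hidden_bias",
                            "output_weights", "output_bias"))
  expect_output(print(fit), "network")

  gfit <- lgwo_nnet(label ~ ., d, optimizer = "gwo", seed = 1)
  expect_s3_class(gfit$opt, "wolf_opt")
  expect_error(lgwo_nnet(x = as.matrix(d[, 1:5]), y = d$V1), "binary")
})
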