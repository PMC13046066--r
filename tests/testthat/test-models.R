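test_that("OLS recovers exact affine relations and constants", {
  set.seed(51)
  x <- matrix(rnorm(400), 200, 2)
  y <- cbind(A = 0.3 + 0.1 * x[, 1] - 0.2 * x[, 2],
             B = rep(0.45, 200))
  fit <- fit_linear_ols(x, y)
  expect_equal(unname(fit$coef[, "A"]), c(0.3, 0.1, -0.2), tolerance = 1e-10)
  expect_equal(unname(fit$coef[, "B"]), c(0.45, 0, 0), tolerance = 1e-10)
  expect_equal(n_parameters(fit), 6)
  # collinear features are rejected
  expect_error(fit_linear_ols(cbind(x[, 1], 2 * x[, 1]), y), "collinear")
  expect_error(fit_linear_ols(x[1:2, ], y[1:2, ]), "at least 3")
})

test_that("OLS coefficients agree with an iterative minimizer of the same loss", {
  set.seed(52)
  x <- matrix(rnorm(600), 300, 2)
  y <- cbind(el = 0.25 + 0.07 * x[, 1] - 0.12 * x[, 2] + rnorm(300, 0, 0.03))
  fit <- fit_linear_ols(x, y)
  obj <- function(b) mean((cbind(1, x) %*% b - y)^2)
  grd <- function(b) 2 * colMeans(as.vector(cbind(1, x) %*% b - y) * cbind(1, x))
  o <- optim(c(0, 0, 0), obj, grd, method = "BFGS",
             control = list(reltol = 1e-15, maxit = 2000))
  expect_equal(unname(fit$coef[, 1]), o$par, tolerance = 1e-6)
})

test_that("linear predictions are affine and unconstrained", {
  set.seed(53)
  x <- matrix(rnorm(200), 100, 2)
  y <- cbind(A = 0.1 + 0.5 * x[, 1], B = 0.9 - 0.4 * x[, 2])
  fit <- fit_linear_ols(x, y)
  expect_equal(unname(predict_linear(fit, c(0, 0))[1, ]),
               unname(fit$coef[1, ]))
  x1 <- c(0.3, -0.2); x2 <- c(-1, 2)
  expect_equal(predict_linear(fit, x1 + x2) + predict_linear(fit, c(0, 0)),
               predict_linear(fit, x1) + predict_linear(fit, x2))
  # far-out inputs can produce physically implausible negative fractions
  expect_lt(min(predict_linear(fit, c(-10, 10))), 0)
})

test_that("network initialization has 3K parameters and is seed-stable", {
  n4 <- init_net(4, seed = 1)
  n5 <- init_net(5, seed = 1)
  expect_equal(n_parameters(n4), 12)
  expect_equal(n_parameters(n5), 15)
  expect_identical(init_net(4, seed = 1), n4)
  expect_false(identical(init_net(4, seed = 2)$W, n4$W))
  expect_true(all(n4$b == 0))
  expect_error(init_net(3), "K must be")
})

test_that("softmax outputs live strictly on the simplex", {
  # zero parameters give the uniform distribution
  n0 <- init_net(4, seed = 1)
  n0$W[] <- 0
  expect_equal(unname(forward_net(n0, c(1.3, -2))[1, ]), rep(0.25, 4))
  set.seed(54)
  net <- init_net(5, seed = 8)
  x <- matrix(rnorm(400, sd = 3), 200, 2)
  p <- forward_net(net, x)
  expect_true(all(p > 0))
  expect_equal(rowSums(p), rep(1, 200), tolerance = 1e-12)
  # shift invariance: adding a constant to every pre-activation
  shifted <- net
  shifted$b <- net$b + 7
  expect_equal(forward_net(shifted, x), forward_net(net, x))
  # overflow safety at extreme pre-activations
  big <- net
  big$W <- net$W * 500
  pb <- forward_net(big, x)
  expect_true(all(is.finite(pb)))
  expect_equal(rowSums(pb), rep(1, 200), tolerance = 1e-12)
  expect_identical(predict_net(net, x), forward_net(net, x))
})

test_that("analytic softmax-MSE gradients match central finite differences", {
  set.seed(55)
  for (K in c(4L, 5L)) {
    net <- init_net(K, seed = K)
    net$b <- rnorm(K, sd = 0.3)
    x <- matrix(rnorm(40), 20, 2)
    y <- forward_net(init_net(K, seed = K + 10), x)  # simplex targets
    ana <- dectmix:::net_loss_grad(net, x, y)
    num <- numeric_net_gradient(net, x, y)
    expect_equal(ana$dW, num$dW, tolerance = 1e-6, ignore_attr = TRUE)
    expect_equal(unname(ana$db), num$db, tolerance = 1e-6)
    expect_equal(ana$loss, mean((forward_net(net, x) - y)^2))
  }
})

test_that("compiled Adam trainer equals the pure-R reference to machine precision", {
  set.seed(56)
  x <- matrix(rnorm(120), 60, 2)
  y <- forward_net(init_net(4, seed = 9), x)
  cfg <- train_config(epochs = 5)
  net0 <- init_net(4, seed = 11)
  seed <- 123
  set.seed(derive_seed(seed, "batches"))
  perms <- vapply(1:5, function(i) sample.int(60), integer(60))
  trained <- train_net(net0, x, y, config = cfg, seed = seed)
  ref <- ref_train_softmax(net0$W, net0$b, x, y, cfg, perms)
  expect_equal(trained$W, ref$W, tolerance = 1e-12)
  expect_equal(trained$b, ref$b, tolerance = 1e-12)
})

test_that("training reduces the loss and fits realizable simplex targets", {
  set.seed(57)
  x <- matrix(rnorm(1600), 800, 2)
  target_net <- init_net(4, seed = 3)
  target_net$b <- c(0.2, -0.1, 0.05, 0)
  y <- forward_net(target_net, x)
  net <- train_net(init_net(4, seed = 21), x, y,
                   config = train_config(epochs = 300), seed = 21)
  expect_lt(net$history$train_mse[nrow(net$history)],
            net$history$train_mse[1])
  # softmax-realizable targets are driven below 1e-4 MSE
  expect_lt(min(net$history$train_mse), 1e-4)
  # trained prediction is deterministic
  expect_identical(predict_net(net, x), predict_net(net, x))
})

test_that("training is reproducible per seed and validates inputs", {
  set.seed(58)
  x <- matrix(rnorm(200), 100, 2)
  y <- forward_net(init_net(4, seed = 2), x)
  cfg <- train_config(epochs = 3)
  a <- train_net(init_net(4, seed = 5), x, y, config = cfg, seed = 99)
  b <- train_net(init_net(4, seed = 5), x, y, config = cfg, seed = 99)
  expect_identical(a$W, b$W)
  expect_error(train_net(init_net(4, seed = 5), x, y + 2, config = cfg),
               "\\[0, 1\\]")
  expect_error(train_config(learning_rate = -1))
})

test_that("models round-trip through JSON files", {
  set.seed(59)
  x <- matrix(rnorm(200), 100, 2)
  y <- cbind(H = 0.1 + 0.02 * x[, 1], O = 0.7 - 0.05 * x[, 2])
  fit <- fit_linear_ols(x, y)
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "lm.json")
  write_model(fit, p1)
  back <- read_model(p1)
  expect_equal(back$coef, fit$coef)
  expect_equal(back$residual_rms, fit$residual_rms)

  ys <- forward_net(init_net(4, seed = 2), x)
  net <- train_net(init_net(4, seed = 5), x, ys,
                   config = train_config(epochs = 2), seed = 1)
  p2 <- file.path(dir, "nn.json")
  write_model(net, p2)
  nback <- read_model(p2)
  expect_equal(nback$W, net$W, ignore_attr = TRUE)
  expect_equal(nback$b, net$b)
  expect_equal(forward_net(nback, x), forward_net(net, x), ignore_attr = TRUE)
})
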