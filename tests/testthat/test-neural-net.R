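# network sizing, scaling, training, gradients, metrics, serialization

test_that("hidden-size rule reproduces the published 8-17 range", {
  expect_identical(hidden_size_candidates(41, 1), 8:17)
  expect_identical(hidden_size_candidates(3, 1), 3:12)   # ceil(2 + a)
  expect_identical(hidden_size_candidates(1, 1), 3:12)   # ceil(sqrt(2) + a)
})

test_that("min-max scaling and its inverse behave per contract", {
  s <- minmax_scale(matrix(c(0, 5, 10), ncol = 1))
  expect_equal(as.numeric(s$scaled), c(0, 0.5, 1))
  set.seed(2)
  X <- matrix(rnorm(30, sd = 5), 10, 3)
  sc <- minmax_scale(X)
  expect_true(all(sc$scaled >= 0 & sc$scaled <= 1))
  expect_equal(inverse_scale(sc$scaled, sc$scaler), X, tolerance = 1e-12)
  expect_warning(cs <- minmax_scale(matrix(7, 2, 1)), "constant")
  expect_equal(as.numeric(cs$scaled), c(0.5, 0.5))
  expect_equal(as.numeric(inverse_scale(cs$scaled, cs$scaler)), c(7, 7))
})

test_that("forward pass matches hand-computed logistic arithmetic on a 2-2-1 toy", {
  p <- list(W = matrix(c(0.1, -0.2, 0.3, 0.4), 2, 2), bh = c(0.05, -0.05),
            V = c(0.7, -0.3), bo = 0.1, n = 2L, h = 2L)
  x <- c(0.5, 0.25)
  z1 <- 1 / (1 + exp(-(0.1 * 0.5 + 0.3 * 0.25 + 0.05)))
  z2 <- 1 / (1 + exp(-(-0.2 * 0.5 + 0.4 * 0.25 - 0.05)))
  yhat <- 0.7 * z1 - 0.3 * z2 + 0.1
  fw <- hospeval:::.bpnn_forward(p, matrix(x, 1))
  expect_equal(fw$yhat, yhat, tolerance = 1e-14)
})

test_that("an all-zero network predicts the scaled-back constant", {
  model <- structure(list(
    params = list(W = matrix(0, 2, 3), bh = c(0, 0), V = c(0, 0), bo = 0,
                  n = 3L, h = 2L),
    x_scaler = list(min = rep(0, 3), max = rep(1, 3)),
    y_scaler = list(min = 2, max = 6),
    hidden = 2L, n_inputs = 3L, config = train_config(),
    trace = data.frame(epoch = 0L, mse = NA_real_), stop_reason = "none"),
    class = "bpnn")
  # scaled output is V.z + bo = 0 -> inverse scale gives y_min
  expect_equal(predict(model, matrix(runif(6), 2, 3)), c(2, 2))
})

test_that("analytic Jacobian matches central finite differences on a 3-2-1 toy", {
  set.seed(4)
  p <- bpnn_init(3, 2, seed = 4)
  X <- matrix(runif(15), 5, 3)
  J <- hospeval:::.bpnn_jacobian(p, X)
  theta <- hospeval:::.bpnn_pack(p)
  eps <- 1e-6
  for (k in seq_along(theta)) {
    tp <- theta; tp[k] <- tp[k] + eps
    tm <- theta; tm[k] <- tm[k] - eps
    fd <- (hospeval:::.bpnn_forward(hospeval:::.bpnn_unpack(tp, 3, 2), X)$yhat -
           hospeval:::.bpnn_forward(hospeval:::.bpnn_unpack(tm, 3, 2), X)$yhat) /
          (2 * eps)
    expect_equal(J[, k], fd, tolerance = 1e-6)
  }
})

test_that("LM training drives a linear target below the MSE goal quickly", {
  set.seed(8)
  X <- matrix(runif(40), 20, 2)
  y <- 3 + 2 * X[, 1] - X[, 2]
  fit <- bpnn_fit(X, y, hidden = 2, train_config(seed = 8))
  expect_identical(fit$stop_reason, "goal")
  expect_lte(fit$trace$mse[nrow(fit$trace)], 1e-5)
  expect_lt(max(fit$trace$epoch), 3000)
  # in-sample predictions consistent with the trace MSE (scaled units)
  yhat <- predict(fit, X)
  scaled_mse <- mean(((y - yhat) / (max(y) - min(y)))^2)
  expect_equal(scaled_mse, fit$trace$mse[nrow(fit$trace)], tolerance = 1e-10)
})

test_that("zero max-epochs returns the seeded initial network unchanged", {
  X <- matrix(runif(20), 10, 2)
  y <- runif(10)
  fit <- bpnn_fit(X, y, hidden = 3, train_config(max_epochs = 0, seed = 5))
  expect_equal(fit$params[c("W", "bh", "V", "bo")],
               bpnn_init(2, 3, seed = 5)[c("W", "bh", "V", "bo")])
  expect_identical(nrow(fit$trace), 1L)
})

test_that("training is deterministic given the seed, and traces never increase", {
  set.seed(10)
  X <- matrix(runif(36), 12, 3)
  y <- sin(2 * X[, 1]) + 0.3 * X[, 2]
  f1 <- bpnn_fit(X, y, 4, train_config(seed = 77))
  f2 <- bpnn_fit(X, y, 4, train_config(seed = 77))
  expect_identical(f1$trace, f2$trace)
  expect_equal(predict(f1, X), predict(f2, X), tolerance = 0)
  expect_true(all(diff(f1$trace$mse) <= 0))
  f3 <- bpnn_fit(X, y, 4, train_config(seed = 78))
  expect_false(identical(f3$trace, f1$trace))
})

test_that("the gradient-descent backend trains and stops on its criteria", {
  set.seed(11)
  X <- matrix(runif(30), 15, 2)
  y <- 0.5 * X[, 1] + 0.2
  fit <- bpnn_fit(X, y, 2, train_config(algorithm = "gd", lr = 0.5,
                                        max_epochs = 500, seed = 11))
  expect_true(fit$stop_reason %in% c("goal", "min_grad", "max_epochs"))
  expect_lt(fit$trace$mse[nrow(fit$trace)], fit$trace$mse[1])
})

test_that("metrics match hand arithmetic and flag zero observations", {
  m0 <- metrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(m0[c("mse", "rmse", "r2", "mape")],
               list(mse = 0, rmse = 0, r2 = 1, mape = 0))
  # y=(1,2), yhat=(2,1): SSres=2, SStot=0.5 -> R2 = 1 - 4 = -3
  m1 <- metrics(c(1, 2), c(2, 1))
  expect_equal(m1$mse, 1)
  expect_equal(m1$rmse, 1)
  expect_equal(m1$r2, -3)
  expect_equal(m1$mape, 75)
  expect_warning(m2 <- metrics(c(0, 1, 2), c(0.5, 1, 2)), "MAPE")
  expect_equal(m2$mape, 0)
  # squared-correlation variant
  expect_equal(metrics(c(1, 2, 3), c(1.1, 2.1, 3.1),
                       r2_method = "squared_cor")$r2, 1, tolerance = 1e-12)
})

test_that("JSON serialization round-trips a trained model", {
  set.seed(12)
  X <- matrix(runif(24), 8, 3)
  y <- X[, 1] - 2 * X[, 3]
  fit <- bpnn_fit(X, y, 2, train_config(seed = 12, max_epochs = 50))
  path <- withr::local_tempfile(fileext = ".json")
  bpnn_to_json(fit, path)
  back <- bpnn_from_json(path)
  expect_equal(predict(back, X), predict(fit, X), tolerance = 1e-12)
  expect_identical(back$stop_reason, fit$stop_reason)
})

test_that("prediction rejects feature-count mismatches", {
  fit <- bpnn_fit(matrix(runif(20), 10, 2), runif(10), 2,
                  train_config(seed = 1, max_epochs = 5))
  expect_error(predict(fit, matrix(runif(9), 3, 3)), "mismatch")
})
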