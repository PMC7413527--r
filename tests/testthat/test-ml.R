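test_that("metrics match hand evaluation and a brute-force loop", {
  m <- regression_metrics(c(1, 2, 3), c(1, 2, 5))
  expect_equal(m$mae, 2 / 3, tolerance = 1e-12)
  expect_equal(m$rmse, sqrt(4 / 3), tolerance = 1e-12)
  expect_equal(m$r2, 1 - 4 / 2, tolerance = 1e-12)

  set.seed(3)
  y <- rnorm(200); yhat <- y + rnorm(200, 0, 0.3)
  loop <- local({
    sse <- 0; sae <- 0; sst <- 0
    for (i in seq_along(y)) {
      sse <- sse + (y[i] - yhat[i])^2
      sae <- sae + abs(y[i] - yhat[i])
      sst <- sst + (y[i] - mean(y))^2
    }
    list(r2 = 1 - sse / sst, mae = sae / length(y),
         rmse = sqrt(sse / length(y)))
  })
  m2 <- regression_metrics(y, yhat)
  expect_equal(m2$r2, loop$r2, tolerance = 1e-12)
  expect_equal(m2$mae, loop$mae, tolerance = 1e-12)
  expect_equal(m2$rmse, loop$rmse, tolerance = 1e-12)
  expect_gte(m2$rmse, m2$mae)

  # analytic anchors: perfect fit and the mean predictor
  expect_equal(regression_metrics(y, y)$r2, 1)
  expect_equal(regression_metrics(y, rep(mean(y), 200))$r2, 0)
})

test_that("k = 1 nearest neighbor memorizes the training set", {
  set.seed(8)
  X <- matrix(rnorm(100 * 3), 100, 3)
  y <- X[, 1]^2 + rnorm(100, 0, 0.1)
  m <- npkresponse:::fit_knn(X, y, k = 1)
  expect_equal(regression_metrics(y, predict(m, X))$r2, 1, tolerance = 1e-9)
  # singleton search space returns that configuration
  spec <- model_spec("knn", search_space = list(k = 7, weight = "uniform"),
                     n_search_iter = 5, seed = 2)
  tuned <- tune_fit(spec, X, y)
  expect_equal(attr(tuned, "hyperparameters")$k, 7)
  expect_equal(attr(tuned, "hyperparameters")$weight, "uniform")
})

test_that("forest and network learn a smooth surface", {
  set.seed(12)
  X <- matrix(runif(400 * 2, -2, 2), 400, 2)
  colnames(X) <- c("a", "b")
  y <- sin(X[, 1]) + 0.5 * X[, 2] + rnorm(400, 0, 0.05)
  rf <- npkresponse:::fit_rf(X, y, n_trees = 30)
  expect_gt(regression_metrics(y, predict(rf, X))$r2, 0.8)
  nn <- npkresponse:::fit_nn(X, y, hidden = 25)
  expect_gt(regression_metrics(y, predict(nn, X))$r2, 0.9)
})

test_that("tuning is reproducible under a fixed seed", {
  set.seed(21)
  X <- matrix(rnorm(120 * 3), 120, 3)
  y <- X %*% c(1, -0.5, 0.2) + rnorm(120, 0, 0.2)
  a <- tune_fit(model_spec("knn", n_search_iter = 6, seed = 5), X, y)
  b <- tune_fit(model_spec("knn", n_search_iter = 6, seed = 5), X, y)
  expect_identical(attr(a, "hyperparameters"), attr(b, "hyperparameters"))
  expect_error(tune_fit(model_spec("knn"), X, rep(1, 120)), "degenerate")
  expect_error(evaluate(a, X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("gaussian process interpolates and its samples are consistent", {
  set.seed(14)
  X <- matrix(seq(-2, 2, length.out = 25), ncol = 1)
  y <- sin(2 * X[, 1])
  gp <- fit_gp(X, y, nu = 1.5, lengthscale = 1, noise = 1e-8)
  # near-zero noise: posterior mean reproduces the observations
  expect_equal(predict(gp, X), y, tolerance = 1e-4)

  Xq <- matrix(seq(-2, 2, length.out = 15), ncol = 1)
  post <- gp_posterior(gp, Xq)
  expect_true(all(diag(post$cov) >= -1e-8))

  gp2 <- fit_gp(X, y, nu = 1.5, lengthscale = 1, noise = 0.05)
  post2 <- gp_posterior(gp2, Xq)
  draws <- gp_draw_samples(post2, 10000, seed = 6)
  mc_mean <- colMeans(draws)
  mc_se <- apply(draws, 2, sd) / sqrt(10000)
  expect_true(all(abs(mc_mean - post2$mean) <= 3 * mc_se + 1e-12))
  # reproducible by seed
  expect_identical(gp_draw_samples(post2, 5, seed = 9),
                   gp_draw_samples(post2, 5, seed = 9))
})

test_that("matern kernels have their textbook shapes", {
  D <- matrix(c(0, 1, 1, 0), 2, 2)
  k05 <- npkresponse:::matern_kernel(D, 1, 0.5)
  expect_equal(k05[1, 2], exp(-1))
  k15 <- npkresponse:::matern_kernel(D, 1, 1.5)
  expect_equal(k15[1, 2], (1 + sqrt(3)) * exp(-sqrt(3)))
  k25 <- npkresponse:::matern_kernel(D, 1, 2.5)
  expect_equal(k25[1, 2], (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)))
  expect_true(all(diag(k15) == 1))
  expect_error(npkresponse:::matern_kernel(D, 1, 3), "nu")
})
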