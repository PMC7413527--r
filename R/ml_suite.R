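#' Regression metrics: R2, MAE, RMSE
#'
#' \deqn{R^2 = 1 - \sum (y_i-\hat y_i)^2 / \sum (y_i-\bar y)^2}
#' \deqn{MAE = \frac1n \sum |y_i-\hat y_i|, \quad
#'       RMSE = \sqrt{\frac1n \sum (y_i-\hat y_i)^2}}
#' R2 is 1 for a perfect fit, 0 for the predictor that always returns the
#' observed mean, and negative for arbitrarily worse models.
#'
#' @param y Observed values.
#' @param yhat Predicted values.
#' @return List with `r2`, `mae`, `rmse`.
#' @export
regression_metrics <- function(y, yhat) {
  stopifnot(length(y) == length(yhat), length(y) > 0)
  res <- y - yhat
  list(r2 = 1 - sum(res^2) / sum((y - mean(y))^2),
       mae = mean(abs(res)),
       rmse = sqrt(mean(res^2)))
}

#' Specify a machine-learning response model and its search space
#'
#' Families: `"knn"` (k, uniform or inverse-distance weights, Euclidean
#' metric), `"rf"` (number of trees, max-features mode), `"nn"` (one hidden
#' tanh layer of 100 or 200 neurons, L2 penalty), `"gp"` (Matern kernel:
#' smoothness nu, lengthscale, noise level). Hyperparameters are tuned by
#' random search with k-fold cross-validation scored by RMSE.
#'
#' @param family One of "knn", "rf", "nn", "gp".
#' @param search_space Named list overriding default ranges; each entry is a
#'   vector of candidate values or a zero-argument function returning one
#'   draw.
#' @param cv_folds Cross-validation folds (default 5).
#' @param n_search_iter Random-search iterations (default 50).
#' @param seed Integer seed.
#' @return A `model_spec` object.
#' @export
model_spec <- function(family = c("knn", "rf", "nn", "gp"),
                       search_space = list(), cv_folds = 5,
                       n_search_iter = 50, seed = 1) {
  family <- match.arg(family)
  stopifnot(cv_folds >= 2, n_search_iter >= 1)
  defaults <- switch(family,
    knn = list(k = 1:25, weight = c("uniform", "inverse")),
    rf = list(n_trees = c(10, 17, 25, 50, 92, 100),
              max_features = c("third", "sqrt", "all")),
    nn = list(hidden = c(100, 200),
              alpha = function() 10^stats::runif(1, -5, -2)),
    gp = list(nu = c(0.5, 1.5, 2.5),
              lengthscale = function() exp(stats::runif(1, log(0.5), log(10))),
              noise = function() exp(stats::runif(1, log(1e-3), log(1)))))
  search_space <- utils::modifyList(defaults, search_space)
  if (any(vapply(search_space, function(s) !is.function(s) && length(s) == 0,
                 logical(1)))) {
    stop("empty search range")
  }
  structure(list(family = family, search_space = search_space,
                 cv_folds = as.integer(cv_folds),
                 n_search_iter = as.integer(n_search_iter),
                 seed = as.integer(seed)),
            class = "model_spec")
}

draw_config <- function(space) {
  lapply(space, function(s) {
    if (is.function(s)) s() else if (length(s) == 1) s else sample(s, 1)
  })
}

fit_family <- function(family, X, y, config) {
  switch(family,
         knn = fit_knn(X, y, k = config$k, weight = config$weight),
         rf = fit_rf(X, y, n_trees = config$n_trees,
                     max_features = config$max_features),
         nn = fit_nn(X, y, hidden = config$hidden, alpha = config$alpha),
         gp = fit_gp(X, y, nu = config$nu, lengthscale = config$lengthscale,
                     noise = config$noise))
}

#' Tune and fit a response model by random-search cross-validation
#'
#' Draws `n_search_iter` hyperparameter configurations from the spec's
#' search space, scores each by k-fold cross-validated RMSE, refits the best
#' configuration on the full training set, and returns the fitted model with
#' the chosen hyperparameters attached.
#'
#' @param spec A [model_spec()].
#' @param X Standardized feature matrix (training rows).
#' @param y Target vector.
#' @return Fitted model (class `npk_<family>`) with attributes
#'   `hyperparameters` and `cv_rmse`.
#' @export
tune_fit <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  X <- as.matrix(X)
  if (stats::sd(y) < 1e-12) stop("degenerate target: zero variance")
  set.seed(spec$seed)
  n <- nrow(X)
  folds <- sample(rep(seq_len(spec$cv_folds), length.out = n))
  configs <- unique(lapply(seq_len(spec$n_search_iter),
                           function(i) draw_config(spec$search_space)))
  best <- NULL
  for (cfg in configs) {
    rmses <- numeric(spec$cv_folds)
    for (f in seq_len(spec$cv_folds)) {
      tr <- folds != f
      m <- fit_family(spec$family, X[tr, , drop = FALSE], y[tr], cfg)
      pred <- predict(m, X[!tr, , drop = FALSE])
      rmses[f] <- sqrt(mean((y[!tr] - pred)^2))
    }
    score <- mean(rmses)
    if (is.null(best) || score < best$score) {
      best <- list(config = cfg, score = score)
    }
  }
  model <- fit_family(spec$family, X, y, best$config)
  attr(model, "hyperparameters") <- best$config
  attr(model, "cv_rmse") <- best$score
  model
}

#' Evaluate a fitted model on a held-out test set
#'
#' @param model Fitted model with a `predict` method.
#' @param X_test Feature matrix of the test rows (same standardization as
#'   training).
#' @param y_test Observed targets.
#' @return Data frame row with r2, mae, rmse and sample counts.
#' @export
evaluate <- function(model, X_test, y_test) {
  if (length(y_test) == 0) stop("empty test set")
  m <- regression_metrics(y_test, predict(model, X_test))
  data.frame(r2 = m$r2, mae = m$mae, rmse = m$rmse, n_test = length(y_test))
}

## ---- k-nearest neighbors --------------------------------------------------

fit_knn <- function(X, y, k = 5, weight = c("uniform", "inverse")) {
  weight <- match.arg(weight)
  stopifnot(k >= 1, k <= nrow(X))
  structure(list(X = as.matrix(X), y = y, k = as.integer(k), weight = weight),
            class = c("npk_knn", "npk_model"))
}

#' @export
predict.npk_knn <- function(object, newdata, ...) {
  Xq <- as.matrix(newdata)
  nn <- FNN::get.knnx(object$X, Xq, k = object$k)
  yn <- matrix(object$y[nn$nn.index], nrow = nrow(Xq))
  if (object$weight == "uniform") return(rowMeans(yn))
  d <- nn$nn.dist
  out <- numeric(nrow(Xq))
  for (i in seq_len(nrow(Xq))) {
    zero <- d[i, ] < 1e-12
    if (any(zero)) {
      out[i] <- mean(yn[i, zero])
    } else {
      w <- 1 / d[i, ]
      out[i] <- sum(w * yn[i, ]) / sum(w)
    }
  }
  out
}

## ---- random forest --------------------------------------------------------

fit_rf <- function(X, y, n_trees = 100,
                   max_features = c("third", "sqrt", "all")) {
  max_features <- match.arg(max_features)
  p <- ncol(as.matrix(X))
  mtry <- switch(max_features,
                 third = max(1L, floor(p / 3)),
                 sqrt = max(1L, floor(sqrt(p))),
                 all = p)
  forest <- fit_forest(X, y, n_trees = n_trees, mtry = mtry, method = "cart")
  class(forest) <- c("npk_rf", class(forest), "npk_model")
  forest
}

## ---- single-hidden-layer neural network (tanh) ----------------------------

fit_nn <- function(X, y, hidden = 100, alpha = 1e-4, maxit = 300,
                   n_restarts = 1) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X); h <- as.integer(hidden)
  mu_y <- mean(y); sd_y <- stats::sd(y)
  ys <- (y - mu_y) / sd_y
  npar <- p * h + h + h + 1

  unpack <- function(w) {
    W1 <- matrix(w[seq_len(p * h)], p, h)
    b1 <- w[p * h + seq_len(h)]
    W2 <- w[p * h + h + seq_len(h)]
    b2 <- w[npar]
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  }
  loss <- function(w) {
    pr <- unpack(w)
    Z <- tanh(sweep(X %*% pr$W1, 2, pr$b1, "+"))
    e <- drop(Z %*% pr$W2) + pr$b2 - ys
    0.5 * mean(e^2) + 0.5 * alpha * (sum(pr$W1^2) + sum(pr$W2^2))
  }
  grad <- function(w) {
    pr <- unpack(w)
    Z <- tanh(sweep(X %*% pr$W1, 2, pr$b1, "+"))
    e <- drop(Z %*% pr$W2) + pr$b2 - ys
    d <- e / n
    gW2 <- drop(crossprod(Z, d)) + alpha * pr$W2
    gb2 <- sum(d)
    dZ <- (d %o% pr$W2) * (1 - Z^2)
    gW1 <- crossprod(X, dZ) + alpha * pr$W1
    gb1 <- colSums(dZ)
    c(as.vector(gW1), gb1, gW2, gb2)
  }
  best <- NULL
  for (r in seq_len(n_restarts)) {
    w0 <- stats::rnorm(npar, 0, sqrt(1 / p))
    fit <- stats::optim(w0, loss, grad, method = "L-BFGS-B",
                        control = list(maxit = maxit))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  structure(list(w = best$par, p = p, hidden = h, alpha = alpha,
                 mu_y = mu_y, sd_y = sd_y, unpack = unpack),
            class = c("npk_nn", "npk_model"))
}

#' @export
predict.npk_nn <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  pr <- object$unpack(object$w)
  Z <- tanh(sweep(X %*% pr$W1, 2, pr$b1, "+"))
  drop(Z %*% pr$W2 + pr$b2) * object$sd_y + object$mu_y
}

## ---- Gaussian process (Matern kernel) -------------------------------------

matern_kernel <- function(D, lengthscale, nu) {
  r <- D / lengthscale
  if (nu == 0.5) {
    exp(-r)
  } else if (nu == 1.5) {
    (1 + sqrt(3) * r) * exp(-sqrt(3) * r)
  } else if (nu == 2.5) {
    (1 + sqrt(5) * r + 5 * r^2 / 3) * exp(-sqrt(5) * r)
  } else {
    stop("nu must be 0.5, 1.5 or 2.5")
  }
}

euclidean_cross <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  sqrt(pmax(d2, 0))
}

chol_jitter <- function(K) {
  for (jit in c(0, 1e-10, 1e-8, 1e-6, 1e-4)) {
    L <- try(chol(K + diag(jit, nrow(K))), silent = TRUE)
    if (!inherits(L, "try-error")) return(L)
  }
  stop("covariance not positive definite after jitter escalation")
}

#' Fit a Gaussian-process regression with a Matern kernel
#'
#' Targets are centered and scaled internally, so the prior mean function is
#' zero on the working scale (as for standardized targets). Rows beyond
#' `max_rows` are subsampled for tractability (cubic cost in n).
#'
#' @param X Feature matrix (standardized).
#' @param y Target vector.
#' @param nu Matern smoothness: 0.5, 1.5 or 2.5 (default 1.5).
#' @param lengthscale Kernel lengthscale (> 0) on the feature scale.
#' @param noise Noise variance added to the kernel diagonal (>= 0).
#' @param max_rows Training-row cap (default 2000).
#' @param seed_subsample Seed used when subsampling.
#' @return A fitted `npk_gp` model.
#' @export
fit_gp <- function(X, y, nu = 1.5, lengthscale = 2, noise = 0.1,
                   max_rows = 2000, seed_subsample = 1) {
  X <- as.matrix(X)
  stopifnot(lengthscale > 0, noise >= 0)
  if (nrow(X) > max_rows) {
    set.seed(seed_subsample)
    keep <- sample.int(nrow(X), max_rows)
    X <- X[keep, , drop = FALSE]
    y <- y[keep]
  }
  mu_y <- mean(y); sd_y <- stats::sd(y)
  ys <- (y - mu_y) / sd_y
  D <- euclidean_cross(X, X)
  K <- matern_kernel(D, lengthscale, nu) + diag(noise, nrow(X))
  U <- chol_jitter(K)
  alpha <- backsolve(U, backsolve(U, ys, transpose = TRUE))
  structure(list(X = X, alpha = alpha, U = U, nu = nu,
                 lengthscale = lengthscale, noise = noise,
                 mu_y = mu_y, sd_y = sd_y),
            class = c("npk_gp", "npk_model"))
}

#' @export
predict.npk_gp <- function(object, newdata, ...) {
  gp_posterior(object, newdata, cov = FALSE)$mean
}

#' Gaussian-process posterior over a set of rows
#'
#' Joint posterior of the latent response surface at `newdata`, on the
#' original target scale. With `cov = TRUE` the full posterior covariance is
#' returned, enabling joint function draws.
#'
#' @param model Fitted GP (from [tune_fit()] with family "gp").
#' @param newdata Feature rows (standardized like the training matrix).
#' @param cov Return the full covariance matrix?
#' @return List with `mean` and (optionally) `cov`.
#' @export
gp_posterior <- function(model, newdata, cov = TRUE) {
  stopifnot(inherits(model, "npk_gp"))
  Xq <- as.matrix(newdata)
  Ks <- matern_kernel(euclidean_cross(Xq, model$X), model$lengthscale,
                      model$nu)
  mean_std <- drop(Ks %*% model$alpha)
  out <- list(mean = mean_std * model$sd_y + model$mu_y)
  if (cov) {
    Kss <- matern_kernel(euclidean_cross(Xq, Xq), model$lengthscale,
                         model$nu)
    V <- backsolve(model$U, t(Ks), transpose = TRUE)
    post_cov <- (Kss - crossprod(V)) * model$sd_y^2
    out$cov <- (post_cov + t(post_cov)) / 2
  }
  out
}

#' Draw joint posterior sample functions from a GP posterior
#'
#' @param posterior Result of [gp_posterior()] with `cov = TRUE`.
#' @param n Number of sample functions.
#' @param seed Integer seed.
#' @return Matrix (n x rows): each row is one sampled response function.
#' @export
gp_draw_samples <- function(posterior, n, seed = 1) {
  stopifnot(!is.null(posterior$cov), n >= 1)
  set.seed(seed)
  m <- length(posterior$mean)
  U <- chol_jitter(posterior$cov)
  Z <- matrix(stats::rnorm(n * m), n, m)
  sweep(Z %*% U, 2, posterior$mean, "+")
}
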