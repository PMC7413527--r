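#' Fertilizer and tuber price model
#'
#' Defaults: $1.20 kg-1 N, $1.10 kg-1 P, $0.90 kg-1 K and $250 Mg-1 for
#' tubers (CDN).
#'
#' @param cost_N,cost_P,cost_K Unit fertilizer costs, $ kg-1.
#' @param tuber_price Tuber price, $ Mg-1.
#' @return A `price_model` list.
#' @export
price_model <- function(cost_N = 1.20, cost_P = 1.10, cost_K = 0.90,
                        tuber_price = 250) {
  stopifnot(cost_N >= 0, cost_P >= 0, cost_K >= 0, tuber_price >= 0)
  structure(list(cost_N = cost_N, cost_P = cost_P, cost_K = cost_K,
                 tuber_price = tuber_price), class = "price_model")
}

#' Monte-Carlo N-P-K dose grid
#'
#' `n_points` random triplets from independent uniform distributions over
#' plausible dose ranges (defaults 0-250 kg N, 0-110 kg P, 0-208 kg K
#' per ha).
#'
#' @param n_points Number of sampled triplets (default 1000).
#' @param bounds Named per-nutrient maxima, kg ha-1.
#' @param seed Integer seed.
#' @return Data frame with columns dose_N, dose_P, dose_K and attribute
#'   `bounds`.
#' @export
dose_grid <- function(n_points = 1000, bounds = c(N = 250, P = 110, K = 208),
                      seed = 1) {
  stopifnot(n_points >= 1, all(bounds > 0))
  set.seed(seed)
  g <- data.frame(dose_N = stats::runif(n_points, 0, bounds[["N"]]),
                  dose_P = stats::runif(n_points, 0, bounds[["P"]]),
                  dose_K = stats::runif(n_points, 0, bounds[["K"]]))
  attr(g, "bounds") <- bounds
  g
}

#' Net return of a fertilized crop
#'
#' Tuber revenue minus fertilizer cost:
#' `yield * tuber_price - (cost_N N + cost_P P + cost_K K)`, $ ha-1.
#'
#' @param predicted_yield Marketable yield, Mg ha-1.
#' @param dose Data frame (dose_N, dose_P, dose_K) or length-3 vector.
#' @param prices A [price_model()].
#' @return Net return, $ ha-1.
#' @export
net_return <- function(predicted_yield, dose, prices = price_model()) {
  if (is.null(dim(dose))) {
    dose <- as.data.frame(as.list(stats::setNames(
      dose, c("dose_N", "dose_P", "dose_K"))))
  }
  predicted_yield * prices$tuber_price -
    (prices$cost_N * dose$dose_N + prices$cost_P * dose$dose_P +
       prices$cost_K * dose$dose_K)
}

# argmax with ties broken by lowest total elemental dose, then lowest N
pick_optimum <- function(objective, grid, tol = 1e-9) {
  cand <- which(objective >= max(objective) - tol)
  total <- grid$dose_N[cand] + grid$dose_P[cand] + grid$dose_K[cand]
  cand[order(total, grid$dose_N[cand])][1]
}

# fixed site row replicated over the grid with dose columns overwritten
stack_fixed_row <- function(fixed_row, grid) {
  stopifnot(nrow(fixed_row) == 1)
  newdata <- fixed_row[rep(1, nrow(grid)), , drop = FALSE]
  newdata$dose_N <- grid$dose_N
  newdata$dose_P <- grid$dose_P
  newdata$dose_K <- grid$dose_K
  rownames(newdata) <- NULL
  newdata
}

recommendation <- function(mode, grid, predictions, objective, opt_idx,
                           extra = list()) {
  rec <- c(list(
    mode = mode,
    optimum = c(dose_N = grid$dose_N[opt_idx], dose_P = grid$dose_P[opt_idx],
                dose_K = grid$dose_K[opt_idx]),
    predicted = predictions[opt_idx],
    objective_at_optimum = objective[opt_idx],
    grid = grid, predictions = predictions, objective = objective),
    extra)
  class(rec) <- "dose_recommendation"
  rec
}

#' @export
print.dose_recommendation <- function(x, ...) {
  ox <- elemental_to_oxide(x$optimum[["dose_P"]], x$optimum[["dose_K"]])
  cat(x$mode, "optimal dose (kg ha-1): N =",
      round(x$optimum[["dose_N"]], 1), " P =",
      round(x$optimum[["dose_P"]], 1), " K =",
      round(x$optimum[["dose_K"]], 1), "\n")
  cat("  (P2O5 =", round(ox$P2O5, 1), ", K2O =", round(ox$K2O, 1), ")\n")
  cat("  predicted output:", format(x$predicted, digits = 4), "\n")
  if (x$mode == "economic") {
    cat("  net return: $", round(x$objective_at_optimum, 2), "ha-1\n")
  }
  if (!is.null(x$percentiles)) {
    cat("  conditional-expectation percentile doses:\n")
    print(round(x$percentiles, 1))
  }
  invisible(x)
}

#' Economic optimal N-P-K dose for a site
#'
#' Replicates the fixed site row (all covariates held constant) across the
#' dose grid, overwrites the dose columns, predicts marketable yield, and
#' returns the triplet maximizing net return. Ties are broken by the lowest
#' total elemental dose, then lowest N.
#'
#' @param model Yield model: a `response_bundle`, `mitscherlich_fit`, or a
#'   function of a raw data frame returning predictions.
#' @param fixed_row One-row data frame of site covariates (dose columns will
#'   be overwritten).
#' @param grid A [dose_grid()].
#' @param prices A [price_model()].
#' @return A `dose_recommendation` (mode "economic").
#' @export
economic_optimum <- function(model, fixed_row, grid,
                             prices = price_model()) {
  if (inherits(model, "response_bundle") && model$target != "yield") {
    stop("economic optimum requires a marketable-yield model, got target '",
         model$target, "'")
  }
  newdata <- stack_fixed_row(fixed_row, grid)
  yhat <- predict_rows(model, newdata)
  net <- net_return(yhat, grid, prices)
  idx <- pick_optimum(net, grid)
  recommendation("economic", grid, yhat, net, idx)
}

#' Agronomic optimal N-P-K dose for a site
#'
#' Same stacking as [economic_optimum()] but maximizes the predicted target
#' itself (yield, a tuber-size balance, or specific gravity) with no cost
#' term.
#'
#' @inheritParams economic_optimum
#' @return A `dose_recommendation` (mode "agronomic").
#' @export
agronomic_optimum <- function(model, fixed_row, grid) {
  newdata <- stack_fixed_row(fixed_row, grid)
  yhat <- predict_rows(model, newdata)
  idx <- pick_optimum(yhat, grid)
  recommendation("agronomic", grid, yhat, yhat, idx)
}

#' Single-nutrient response curve at fixed site conditions
#'
#' Varies one dose over `dose_range` with the other two held at the fixed
#' row's values. Smooth models (Mitscherlich, NN, GP) give continuous
#' curves; KNN and RF give stepped curves.
#'
#' @param model Prediction model (see [economic_optimum()]).
#' @param fixed_row One-row data frame of site covariates.
#' @param nutrient "N", "P" or "K".
#' @param dose_range Length-2 range of the varied dose, kg ha-1.
#' @param n_points Number of curve points (default 100).
#' @return Data frame with columns `dose` and `prediction`.
#' @export
response_curve <- function(model, fixed_row, nutrient = c("N", "P", "K"),
                           dose_range, n_points = 100) {
  nutrient <- match.arg(nutrient)
  doses <- seq(dose_range[1], dose_range[2], length.out = n_points)
  newdata <- fixed_row[rep(1, n_points), , drop = FALSE]
  newdata[[paste0("dose_", nutrient)]] <- doses
  rownames(newdata) <- NULL
  data.frame(dose = doses, prediction = predict_rows(model, newdata))
}

#' Distribution of optimal doses from Gaussian-process posterior samples
#'
#' Draws `n_samples` joint posterior response functions over the dose grid
#' (full covariance, so each draw is a coherent surface), computes the
#' economic (or agronomic) optimal triplet of every sampled function, and
#' summarizes the per-sample optima: conditional-expectation percentile
#' doses, modal histogram bin per nutrient, and the optimum of the posterior
#' mean curve (which need not coincide with the most likely sampled
#' optimum).
#'
#' @param model A `response_bundle` wrapping a GP, or a fitted `npk_gp`
#'   (then `fixed_row` must already be on the model's feature scale).
#' @param fixed_row One-row data frame of site covariates.
#' @param grid A [dose_grid()].
#' @param n_samples Number of posterior draws (default 1000, >= 2).
#' @param mode "economic" (needs a yield target) or "agronomic".
#' @param prices A [price_model()] (economic mode).
#' @param seed Integer seed for the posterior draws.
#' @param percentiles Reported conditional-expectation percentiles.
#' @param n_bins Equal-width histogram bins per nutrient (default 25).
#' @return A `dose_recommendation` with `per_sample_optima` (n_samples x 3),
#'   `percentiles` (matrix percentile x nutrient), `modal_bin` and
#'   `mean_curve_optimum`.
#' @export
sample_optimal_doses <- function(model, fixed_row, grid, n_samples = 1000,
                                 mode = c("economic", "agronomic"),
                                 prices = price_model(), seed = 1,
                                 percentiles = c(50, 80), n_bins = 25) {
  mode <- match.arg(mode)
  if (n_samples < 2) stop("need at least 2 posterior samples")
  gp <- if (inherits(model, "response_bundle")) model$model else model
  if (!inherits(gp, "npk_gp")) {
    stop("posterior dose sampling requires a Gaussian-process model")
  }
  newdata <- stack_fixed_row(fixed_row, grid)
  if (inherits(model, "response_bundle")) {
    z <- apply_standardizer(model$standardizer, newdata)
    Xq <- as.matrix(z[, model$features, drop = FALSE])
  } else {
    Xq <- as.matrix(newdata)
  }
  post <- gp_posterior(gp, Xq, cov = TRUE)
  draws <- gp_draw_samples(post, n_samples, seed = seed)

  objective_of <- function(pred) {
    if (mode == "economic") net_return(pred, grid, prices) else pred
  }
  opt_idx <- apply(draws, 1, function(pred) {
    pick_optimum(objective_of(pred), grid)
  })
  per_sample <- cbind(dose_N = grid$dose_N[opt_idx],
                      dose_P = grid$dose_P[opt_idx],
                      dose_K = grid$dose_K[opt_idx])

  mean_obj <- objective_of(post$mean)
  mean_idx <- pick_optimum(mean_obj, grid)

  bounds <- attr(grid, "bounds")
  if (is.null(bounds)) {
    bounds <- c(N = max(grid$dose_N), P = max(grid$dose_P),
                K = max(grid$dose_K))
  }
  modal_bin <- sapply(c("N", "P", "K"), function(nu) {
    breaks <- seq(0, bounds[[nu]], length.out = n_bins + 1)
    counts <- table(cut(per_sample[, paste0("dose_", nu)], breaks,
                        include.lowest = TRUE))
    b <- unname(which.max(counts))
    c(bin = b, center = (breaks[b] + breaks[b + 1]) / 2)
  })
  pct <- sapply(c("dose_N", "dose_P", "dose_K"), function(cl) {
    vapply(percentiles, function(x) {
      conditional_expectation_dose(per_sample[, cl], x)
    }, numeric(1))
  })
  rownames(pct) <- paste0("p", percentiles)

  recommendation(mode, grid, post$mean, mean_obj, mean_idx, extra = list(
    per_sample_optima = per_sample,
    percentiles = pct,
    modal_bin = modal_bin,
    mean_curve_optimum = c(dose_N = grid$dose_N[mean_idx],
                           dose_P = grid$dose_P[mean_idx],
                           dose_K = grid$dose_K[mean_idx]),
    n_samples = n_samples))
}

#' Conditional-expectation percentile dose
#'
#' The x-th conditional expectation dose is the x-th percentile of the
#' per-posterior-sample optimal doses of one nutrient: the dose that is
#' sufficient (meets or exceeds the sampled optimum) x percent of the time.
#' Linear interpolation between order statistics is used.
#'
#' @param per_sample_optima Numeric vector of per-sample optimal doses for
#'   one nutrient.
#' @param x Percentile in (0, 100\].
#' @return Dose at the x-th percentile; non-decreasing in x.
#' @export
conditional_expectation_dose <- function(per_sample_optima, x) {
  if (length(per_sample_optima) == 0) stop("empty sample of optima")
  if (x <= 0 || x > 100) stop("percentile must lie in (0, 100]")
  stats::quantile(per_sample_optima, x / 100, names = FALSE, type = 7)
}
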