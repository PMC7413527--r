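truth_R <- c(N = 0.015, P = 0.02, K = 0.01)
truth_E <- c(N = 40, P = 30, K = 80)
truth_model <- function(newdata) {
  mitscherlich_surface(45, truth_R, truth_E,
                       newdata[, c("dose_N", "dose_P", "dose_K")])
}
site_row <- data.frame(dose_N = 0, dose_P = 0, dose_K = 0)

test_that("net return decomposes exactly into revenue minus cost", {
  pr <- price_model()
  expect_equal(net_return(0, c(0, 0, 0), pr), 0)
  expect_equal(net_return(30, c(100, 50, 100), pr), 7235)
  # decomposition identity and strict decrease in dose at fixed yield
  dose <- data.frame(dose_N = c(10, 50), dose_P = c(5, 20),
                     dose_K = c(0, 80))
  cost <- 1.2 * dose$dose_N + 1.1 * dose$dose_P + 0.9 * dose$dose_K
  expect_equal(net_return(25, dose, pr) + cost, rep(25 * 250, 2))
  expect_lt(net_return(25, c(10, 10, 10), pr)[1],
            net_return(25, c(9, 10, 10), pr)[1])
})

test_that("flat models are driven to the cheapest grid point", {
  grid <- dose_grid(500, seed = 2)
  flat <- function(newdata) rep(30, nrow(newdata))
  rec <- economic_optimum(flat, site_row, grid)
  cost <- 1.2 * grid$dose_N + 1.1 * grid$dose_P + 0.9 * grid$dose_K
  expect_equal(unname(rec$optimum),
               unname(unlist(grid[which.min(cost), ])))
  # agronomic mode on a flat model: tie broken at lowest total dose, then N
  reca <- agronomic_optimum(flat, site_row, grid)
  tot <- grid$dose_N + grid$dose_P + grid$dose_K
  expect_equal(sum(reca$optimum), min(tot))
})

test_that("zero prices collapse the economic onto the agronomic optimum", {
  grid <- dose_grid(1000, seed = 3)
  free <- price_model(0, 0, 0, 250)  # zero fertilizer costs
  eco <- economic_optimum(truth_model, site_row, grid, free)
  agr <- agronomic_optimum(truth_model, site_row, grid)
  expect_equal(eco$optimum, agr$optimum)
})

test_that("random-grid optimum approaches the exhaustive-lattice oracle", {
  lattice <- expand.grid(dose_N = seq(0, 250, length.out = 30),
                         dose_P = seq(0, 110, length.out = 30),
                         dose_K = seq(0, 208, length.out = 30))
  net_lat <- net_return(truth_model(lattice), lattice, price_model())
  best_lat <- max(net_lat)
  gaps <- vapply(c(100, 10000), function(np) {
    rec <- economic_optimum(truth_model, site_row,
                            dose_grid(np, seed = 11), price_model())
    best_lat - rec$objective_at_optimum
  }, numeric(1))
  # the lattice bounds the random grid from above; the gap shrinks with n
  expect_true(all(gaps >= -1e-9))
  expect_lt(gaps[2], gaps[1])
})

test_that("response curves trace the closed form and respect ranges", {
  rc <- response_curve(truth_model, site_row, "N", c(0, 260), n_points = 40)
  closed <- 45 * (1 - exp(-truth_R[["N"]] * (truth_E[["N"]] + rc$dose))) *
    (1 - exp(-truth_R[["P"]] * truth_E[["P"]])) *
    (1 - exp(-truth_R[["K"]] * truth_E[["K"]]))
  expect_equal(rc$prediction, closed, tolerance = 1e-9)
  expect_equal(range(rc$dose), c(0, 260))
  flat <- response_curve(function(nd) rep(2, nrow(nd)), site_row, "K",
                         c(0, 100), n_points = 10)
  expect_true(all(flat$prediction == 2))
})

test_that("agronomic dose dominates economic dose for the truth surface", {
  lattice <- expand.grid(dose_N = seq(0, 250, length.out = 40),
                         dose_P = seq(0, 110, length.out = 40),
                         dose_K = seq(0, 208, length.out = 40))
  y <- truth_model(lattice)
  i_agr <- which.max(y)
  i_eco <- which.max(net_return(y, lattice, price_model()))
  expect_gte(lattice$dose_N[i_agr], lattice$dose_N[i_eco])
})

test_that("percentile doses follow order statistics and are monotone", {
  expect_equal(conditional_expectation_dose(rep(42, 10), 80), 42)
  expect_equal(conditional_expectation_dose(c(0, 100, 200, 300, 400), 50),
               200)
  set.seed(6)
  v <- runif(200, 0, 250)
  xs <- c(5, 25, 50, 55, 80, 95, 100)
  ds <- vapply(xs, function(x) conditional_expectation_dose(v, x),
               numeric(1))
  expect_true(all(diff(ds) >= 0))
  expect_error(conditional_expectation_dose(numeric(0), 50), "empty")
  expect_error(conditional_expectation_dose(v, 0), "\\(0, 100\\]")
})

test_that("monotone posterior surfaces pile sampled optima at the edge", {
  set.seed(44)
  Xtr <- as.matrix(dose_grid(150, seed = 8))
  y <- 0.02 * Xtr[, "dose_N"] + rnorm(150, 0, 0.05)
  gp <- fit_gp(Xtr, y, nu = 1.5, lengthscale = 150, noise = 1e-4)
  grid <- dose_grid(300, seed = 9)
  rec <- sample_optimal_doses(gp, site_row, grid, n_samples = 200,
                              mode = "agronomic", seed = 10)
  edge_share <- mean(rec$per_sample_optima[, "dose_N"] > 0.9 * 250)
  expect_gt(edge_share, 0.8)
  expect_error(sample_optimal_doses(gp, site_row, grid, n_samples = 1),
               "at least 2")
  expect_error(sample_optimal_doses(truth_model, site_row, grid),
               "Gaussian-process")
})
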