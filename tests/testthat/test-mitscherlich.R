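test_that("surface evaluates the closed form and respects its limits", {
  # independent literal arithmetic of the three-factor product
  A <- 40; R <- c(N = 0.02, P = 0.03, K = 0.01); E <- c(N = 50, P = 30, K = 80)
  dose <- c(100, 40, 60)
  hand <- 40 * (1 - exp(-3)) * (1 - exp(-2.1)) * (1 - exp(-1.4))
  expect_equal(mitscherlich_surface(A, R, E, dose), hand, tolerance = 1e-12)
  expect_equal(hand, 25.12908, tolerance = 1e-5)

  # saturation to A and zero at zero supply
  expect_equal(mitscherlich_surface(A, R, E, c(1e5, 1e5, 1e5)), A,
               tolerance = 1e-6)
  expect_equal(mitscherlich_surface(A, R, c(N = 0, P = 0, K = 0), c(0, 0, 0)),
               0)
  expect_error(mitscherlich_surface(-1, R, E, dose), "A > 0")
  expect_error(mitscherlich_surface(A, c(N = 0, P = 0.1, K = 0.1), E, dose),
               "R > 0")
})

test_that("surface is monotone in every dose and bounded by A", {
  A <- 45; R <- c(N = 0.015, P = 0.02, K = 0.01); E <- c(N = 40, P = 30, K = 80)
  g <- expand.grid(dose_N = seq(0, 260, 20), dose_P = seq(0, 130, 26),
                   dose_K = seq(0, 350, 50))
  y <- mitscherlich_surface(A, R, E, g)
  expect_true(all(y >= 0 & y < A))
  for (nu in c("dose_N", "dose_P", "dose_K")) {
    others <- setdiff(names(g), nu)
    for (key in split(seq_len(nrow(g)), g[others])) {
      ord <- key[order(g[key, nu])]
      expect_true(all(diff(y[ord]) >= -1e-12))
    }
  }
})

test_that("with two nutrients saturated the surface is univariate", {
  A <- 45; R <- c(N = 0.015, P = 0.02, K = 0.01); E <- c(N = 40, P = 30, K = 80)
  dn <- seq(0, 260, length.out = 30)
  tri <- mitscherlich_surface(A, R, E,
                              data.frame(dose_N = dn, dose_P = 5e4,
                                         dose_K = 5e4))
  uni <- A * (1 - exp(-R[["N"]] * (E[["N"]] + dn)))
  expect_equal(tri, uni, tolerance = 1e-6)
})

test_that("noiseless parameter recovery and level-0 consistency", {
  cfg <- recovery_config(noise_sd = 0, block_sd = 0, seed = 19, n_trials = 8)
  d <- generate_trials(cfg)
  fit <- fit_mitscherlich(d$trials, n_starts = 2, seed = 4)
  tr <- d$truth$params
  expect_lt(abs(fit$params$A - tr$A) / tr$A, 0.01)
  expect_true(all(abs(fit$params$R - tr$R) / tr$R < 0.05))
  expect_true(all(abs(fit$params$E - tr$E) / tr$E < 0.05))

  # level-0 prediction: R^2 = 1 on the noiseless set, invariant to trial id
  pred <- predict_level0(fit, d$trials)
  expect_gt(regression_metrics(d$trials$yield, pred)$r2, 1 - 1e-6)
  shuffled <- d$trials
  shuffled$trial <- rev(shuffled$trial)
  expect_equal(predict_level0(fit, shuffled), pred)
  # and equals the surface applied row-wise at the fitted parameters
  direct <- mitscherlich_surface(fit$params$A, fit$params$R, fit$params$E,
                                 d$trials[, c("dose_N", "dose_P", "dose_K")])
  expect_equal(pred, direct, tolerance = 1e-9)
})

test_that("nutrients without dose gradients are flagged unidentifiable", {
  d <- generate_trials(generator_config(n_trials = 4, trial_type = "N",
                                        noise_sd = 0.5, block_sd = 0,
                                        seed = 23))
  # force P and K constant across all plots
  d$trials$dose_P <- 50
  d$trials$dose_K <- 100
  fit <- fit_mitscherlich(d$trials, n_starts = 2, seed = 5)
  expect_setequal(fit$diagnostics$unidentified, c("P", "K"))
  expect_error(fit_mitscherlich(d$trials[d$trials$trial == 1, ]),
               "2 groups")
})

test_that("parameters serialize and read back", {
  cfg <- recovery_config(noise_sd = 0, block_sd = 0, seed = 19, n_trials = 8)
  d <- generate_trials(cfg)
  fit <- fit_mitscherlich(d$trials, n_starts = 1, seed = 4)
  path <- withr::local_tempfile(fileext = ".json")
  write_mitscherlich(fit, path)
  back <- read_mitscherlich(path)
  expect_equal(back$params$A, fit$params$A, tolerance = 1e-12)
  expect_equal(back$links$R, "softplus")
})
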