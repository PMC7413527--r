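test_that("design shape, determinism and dose bounds hold", {
  cfg <- small_config()
  d <- generate_trials(cfg)
  expect_equal(nrow(d$trials), 4 * 3 * 5)

  # identical seeds give identical output
  d2 <- generate_trials(small_config())
  expect_identical(d$trials, d2$trials)
  expect_identical(d$weather, d2$weather)

  # RCBD balance: every block of a trial has each treatment exactly once
  tab <- table(d$trials$trial, d$trials$block, d$trials$treatment)
  expect_true(all(tab == 1))

  bounds <- cfg$dose_bounds
  expect_true(all(d$trials$dose_N >= 0 & d$trials$dose_N <= bounds[["N"]]))
  expect_true(all(d$trials$dose_P >= 0 & d$trials$dose_P <= bounds[["P"]]))
  expect_true(all(d$trials$dose_K >= 0 & d$trials$dose_K <= bounds[["K"]]))
  expect_true(all(d$trials$yield >= 0))

  # factorial designs vary all three nutrients
  df <- generate_trials(generator_config(n_trials = 2, trial_type = "factorial",
                                         treatments_per_trial = 6, seed = 3))
  per_trial_var <- aggregate(cbind(dose_N, dose_P, dose_K) ~ trial,
                             df$trials, function(v) diff(range(v)))
  expect_true(all(per_trial_var[, -1] > 0))

  expect_error(generator_config(n_trials = 0), "n_trials")
  expect_error(generator_config(treatments_per_trial = 3),
               "treatments_per_trial")
})

test_that("noiseless yields equal the ground-truth surface", {
  cfg <- small_config(noise_sd = 0, block_sd = 0)
  d <- generate_trials(cfg)
  expected <- mitscherlich_surface(d$truth$params$A, d$truth$params$R,
                                   d$truth$params$E,
                                   d$trials[, c("dose_N", "dose_P", "dose_K")])
  expect_equal(d$trials$yield, expected, tolerance = 1e-12)

  # marginal response to the tested nutrient is non-decreasing
  for (tr in unique(d$trials$trial)) {
    sub <- d$trials[d$trials$trial == tr & d$trials$block == 1, ]
    sub <- sub[order(sub$dose_N), ]
    expect_true(all(diff(sub$yield) >= -1e-12))
  }
})

test_that("covariate effects on the asymptote propagate to yields", {
  cfg <- small_config(noise_sd = 0, block_sd = 0,
                      cov_A = c(density = 8, ph = 6))
  d <- generate_trials(cfg)
  A_row <- 45 + 8 * (d$trials$density - 36000) / 10000 +
    6 * (d$trials$ph - 5.7)
  f <- mitscherlich_surface(1, d$truth$params$R, d$truth$params$E,
                            d$trials[, c("dose_N", "dose_P", "dose_K")])
  expect_equal(d$trials$yield, A_row * f, tolerance = 1e-12)
})

test_that("quality targets close to one and stay in physical ranges", {
  d <- generate_trials(small_config())
  s <- d$trials$frac_S + d$trials$frac_M + d$trials$frac_L
  expect_true(all(abs(s - 1) < 1e-9))
  expect_true(all(d$trials$sg >= 1.040 & d$trials$sg <= 1.120))
})

test_that("large-fraction censoring hits the requested rate", {
  set.seed(9)
  big <- as.data.frame(random_composition(10000, 3))
  names(big) <- c("frac_S", "frac_M", "frac_L")
  big$censored_L <- FALSE

  expect_identical(censor_large_fraction(big, 0), big)
  all_c <- censor_large_fraction(big, 1, seed = 2)
  expect_true(all(all_c$frac_L == 0))
  expect_true(all(abs(all_c$frac_S + all_c$frac_M - 1) < 1e-9))

  part <- censor_large_fraction(big, 0.21, seed = 3)
  share <- mean(part$frac_L == 0)
  expect_lt(abs(share - 0.21), 0.02)
  expect_equal(part$censored_L, part$frac_L == 0)
  expect_error(censor_large_fraction(big, 1.2), "\\[0, 1\\]")
})

test_that("datasets serialize to plain-text files", {
  d <- generate_trials(small_config())
  dir <- withr::local_tempdir()
  paths <- write_trial_data(d, dir)
  expect_true(all(file.exists(paths)))
  back <- utils::read.csv(paths[1])
  expect_equal(nrow(back), nrow(d$trials))
  truth <- jsonlite::read_json(paths[3], simplifyVector = TRUE)
  expect_equal(truth$params$A, d$truth$params$A)
})
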