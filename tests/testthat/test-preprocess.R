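frame_fixture <- local({
  d <- generate_trials(recovery_config(noise_sd = 1, block_sd = 1, n_trials = 8))
  make_model_frame(d$trials, d$weather)
})

test_that("model frame carries features, balances and targets", {
  fr <- frame_fixture
  feats <- feature_columns(fr)
  expect_true(all(feats %in% names(fr)))
  expect_false(anyNA(fr[, c(feats, attr(fr, "targets"))]))

  # texture balance of the first row equals a direct transform
  sc <- potato_balance_schemes()$texture
  d <- generate_trials(recovery_config(noise_sd = 1, block_sd = 1, n_trials = 8))
  r1 <- d$trials[d$trials$plot_id == fr$plot_id[1], ]
  b <- ilr_transform(c(sand = r1$sand, silt = r1$silt, clay = r1$clay,
                       C = r1$c_pct), sc)
  expect_equal(unname(fr$bal_texture_C[1]), unname(b[1, 1]),
               tolerance = 1e-12)

  # unknown maturity class warns and encodes as all-zero
  bad <- d$trials
  bad$maturity_class[1] <- "exotic"
  expect_warning(fr2 <- make_model_frame(bad, d$weather), "exotic")
  mat_cols <- grep("^mat_", names(fr2), value = TRUE)
  expect_equal(sum(fr2[1, mat_cols]), 0)
})

test_that("standardizer uses training statistics only", {
  fr <- frame_fixture
  sp <- split_blocks(fr, 0.7, seed = 3)
  feats <- setdiff(feature_columns(fr), grep("^mat_", names(fr), value = TRUE))
  std <- fit_standardizer(sp$train, feats)
  ztr <- apply_standardizer(std, sp$train)
  zte <- apply_standardizer(std, sp$test)
  mu <- vapply(feats, function(cl) mean(ztr[[cl]]), numeric(1))
  v <- vapply(feats, function(cl) var(ztr[[cl]]), numeric(1))
  expect_true(all(abs(mu) < 1e-9))
  expect_true(all(abs(v - 1) < 1e-6))
  # test rows transformed with the same statistics, not their own
  expect_equal(zte$dose_N,
               (sp$test$dose_N - std$mean[["dose_N"]]) / std$sd[["dose_N"]])
  expect_warning(fit_standardizer(data.frame(a = rep(1, 5)), "a"),
                 "zero-variance")
})

test_that("z-score outlier removal drops planted outliers only", {
  set.seed(31)
  tab <- data.frame(sg = rnorm(1000, 1.08, 0.005), other = rnorm(1000))
  tab$sg[17] <- mean(tab$sg) + 4 * sd(tab$sg)
  out <- remove_outliers_zscore(tab, "sg", threshold = 3)
  expect_false(17 %in% as.integer(rownames(out)))
  expect_true(attr(out, "n_dropped") >= 1)

  # identical values: skipped with a warning, nothing dropped
  same <- data.frame(x = rep(2, 10))
  expect_warning(kept <- remove_outliers_zscore(same, "x"), "zero-variance")
  expect_equal(nrow(kept), 10)

  # an effectively infinite threshold keeps everything
  expect_equal(nrow(remove_outliers_zscore(tab, c("sg", "other"),
                                           threshold = 1e9)), 1000)
})

test_that("block-level split is disjoint, stratified and deterministic", {
  # 10 equal blocks in one stratum -> exactly 7 / 3
  tab <- data.frame(trial = rep(1:5, each = 20),
                    block = rep(rep(1:2, each = 10), 5),
                    trial_type = "N")
  sp <- split_blocks(tab, 0.7, seed = 4)
  expect_equal(length(attr(sp, "train_blocks")), 7)
  expect_equal(length(attr(sp, "test_blocks")), 3)
  expect_length(intersect(attr(sp, "train_blocks"),
                          attr(sp, "test_blocks")), 0)

  sp2 <- split_blocks(tab, 0.7, seed = 4)
  expect_identical(sp$train, sp2$train)

  # stratified by trial type on a generated mixed frame, share within 5 pp
  fr <- frame_fixture
  spf <- split_blocks(fr, 0.7, seed = 9)
  expect_lt(abs(nrow(spf$train) / nrow(fr) - 0.7), 0.05)
  tt <- paste(spf$train$trial, spf$train$block)
  te <- paste(spf$test$trial, spf$test$block)
  expect_length(intersect(tt, te), 0)
  expect_setequal(unique(spf$train$trial_type), unique(fr$trial_type))

  # a stratum with a single block goes to training with a warning
  solo <- data.frame(trial = c(1, 1, 2, 2), block = c(1, 2, 1, 1),
                     trial_type = c("N", "N", "K", "K"))
  expect_warning(sps <- split_blocks(solo, 0.7, seed = 1), "< 2 blocks")
  expect_true(all(sps$train$trial_type[sps$train$trial == 2] == "K"))
})

test_that("feature importance finds the dose driving the ground truth", {
  d <- generate_trials(generator_config(n_trials = 10, trial_type = "N",
                                        noise_sd = 0, block_sd = 0, seed = 13))
  fr <- make_model_frame(d$trials, d$weather)
  fr$pure_noise <- rnorm(nrow(fr))
  feats <- c(feature_columns(fr), "pure_noise")
  scores <- rank_features(fr, "yield", features = feats, n_trees = 50,
                          seed = 2)
  expect_equal(sum(scores), 1, tolerance = 1e-9)
  expect_true(all(scores >= 0))
  expect_true(all(diff(scores) <= 0))
  expect_equal(names(scores)[1], "dose_N")
  expect_lt(scores["pure_noise"], scores["dose_N"])
  expect_error(rank_features(transform(fr, yield = 1), "yield",
                             features = feats), "constant target")
})
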