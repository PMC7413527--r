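#' Configuration for the synthetic field-trial generator
#'
#' Describes a set of randomized complete block fertilizer trials: each trial
#' has `blocks_per_trial` complete blocks of `treatments_per_trial` dose
#' treatments. Single-nutrient trials (`trial_type` "N", "P" or "K") vary the
#' tested nutrient over evenly spaced steps from 0 to its bound while the
#' other two are held at a trial-level grower dose; "factorial" trials vary
#' all three. Yields follow a tri-variate Mitscherlich surface with a
#' block-level random intercept on the asymptote plus Gaussian noise.
#'
#' @param n_trials Number of trials (sites).
#' @param blocks_per_trial Complete blocks per trial (default 3).
#' @param treatments_per_trial Treatments per trial, between 4 and 6.
#' @param trial_type "N", "P", "K" or "factorial"; length 1 or `n_trials`.
#' @param dose_bounds Named vector of per-nutrient maxima, kg ha-1
#'   (defaults N 260, P 130, K 350).
#' @param noise_sd Plot-level yield noise SD, Mg ha-1 (default 2).
#' @param block_sd SD of the block random intercept on the asymptote,
#'   Mg ha-1 (default 2).
#' @param quality_noise_sd Noise SD on the two tuber-size balances (the SG
#'   noise is `quality_noise_sd / 50`).
#' @param true_A,true_R,true_E Ground-truth Mitscherlich parameters:
#'   asymptote (Mg ha-1), rates (ha kg-1) and environment fertilizer
#'   equivalents (kg ha-1), named N/P/K for the vectors.
#' @param cov_A Named vector `c(density =, ph =)` of additive covariate
#'   effects on the asymptote (Mg ha-1 per standardized unit: density is
#'   scaled as (density - 36000)/10000, pH as pH - 5.7). Default zero
#'   (constant asymptote); nonzero values emulate site-driven response
#'   variation.
#' @param covariate_ranges Named list of c(low, high) ranges for trial-level
#'   covariates; unspecified entries take defaults spanning the observed
#'   ranges of Quebec potato trials (pH 5.2-6.2, Mehlich-3 P 20-350 mg kg-1,
#'   etc.).
#' @param study_year Calendar year of the study season.
#' @param seed Integer seed; identical configs generate identical data.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_trials = 8,
                             blocks_per_trial = 3,
                             treatments_per_trial = 5,
                             trial_type = "N",
                             dose_bounds = c(N = 260, P = 130, K = 350),
                             noise_sd = 2,
                             block_sd = 2,
                             quality_noise_sd = 0.15,
                             true_A = 45,
                             true_R = c(N = 0.015, P = 0.02, K = 0.01),
                             true_E = c(N = 40, P = 30, K = 80),
                             cov_A = c(density = 0, ph = 0),
                             covariate_ranges = list(),
                             study_year = 2017,
                             seed = 42) {
  stopifnot(n_trials >= 1, blocks_per_trial >= 1,
            treatments_per_trial >= 4, treatments_per_trial <= 6,
            all(dose_bounds > 0), noise_sd >= 0, block_sd >= 0,
            true_A > 0, all(true_R > 0), all(true_E >= 0))
  if (!length(trial_type) %in% c(1L, n_trials)) {
    stop("trial_type must have length 1 or n_trials")
  }
  if (!all(trial_type %in% c("N", "P", "K", "factorial"))) {
    stop("trial_type must be one of N, P, K, factorial")
  }
  defaults <- list(
    ph = c(5.2, 6.2), p_m3 = c(20, 350), k_m3 = c(70, 270),
    ca_m3 = c(800, 2500), mg_m3 = c(60, 300), al_m3 = c(1200, 2900),
    c_pct = c(1, 4), sand = c(40, 85), clay = c(2, 15),
    density = c(31000, 44000), season_length = c(102, 131))
  covariate_ranges <- utils::modifyList(defaults, covariate_ranges)
  structure(list(n_trials = as.integer(n_trials),
                 blocks_per_trial = as.integer(blocks_per_trial),
                 treatments_per_trial = as.integer(treatments_per_trial),
                 trial_type = rep_len(trial_type, n_trials),
                 dose_bounds = dose_bounds,
                 noise_sd = noise_sd, block_sd = block_sd,
                 quality_noise_sd = quality_noise_sd,
                 true_A = true_A, true_R = true_R, true_E = true_E,
                 cov_A = cov_A,
                 covariate_ranges = covariate_ranges,
                 study_year = as.integer(study_year),
                 seed = as.integer(seed)),
            class = "generator_config")
}

runif_range <- function(n, range) stats::runif(n, range[1], range[2])

#' Generate a synthetic field-trial dataset with known ground truth
#'
#' Produces one plot-level table (doses, soil and management covariates,
#' yield, tuber size fractions, specific gravity), a daily weather series per
#' site spanning the study season plus five historical seasons, and the
#' ground truth used for generation (Mitscherlich parameters, block effects,
#' quality-target coefficient models) so that parameter recovery can be
#' tested.
#'
#' @param config A [generator_config()].
#' @return List with elements `trials` (data.frame, one row per plot),
#'   `weather` (data.frame: site_id, date, rain_mm, tmean_c) and `truth`.
#' @export
generate_trials <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  cr <- config$covariate_ranges
  nt <- config$n_trials
  nb <- config$blocks_per_trial
  ntr <- config$treatments_per_trial
  bounds <- config$dose_bounds

  # trial-level covariates
  sand <- runif_range(nt, cr$sand)
  clay <- runif_range(nt, cr$clay)
  silt <- 100 - sand - clay
  mem <- matrix(stats::rgamma(3 * nt, shape = 2), nt, 3)
  mem <- mem / rowSums(mem)
  colnames(mem) <- c("mem_loamy_gleyed", "mem_sandy_gleyed", "mem_podzolized")
  maturity <- sample(c("early", "early_mid", "mid", "mid_late", "late"),
                     nt, replace = TRUE,
                     prob = c(0.04, 0.13, 0.62, 0.12, 0.09))
  season_length <- round(runif_range(nt, cr$season_length))
  planting_day <- sample(10:25, nt, replace = TRUE)
  planting <- as.Date(sprintf("%d-05-%02d", config$study_year, planting_day))
  harvest <- planting + season_length
  trial_cov <- data.frame(
    trial = seq_len(nt),
    trial_type = config$trial_type,
    sand = sand, silt = silt, clay = clay,
    c_pct = runif_range(nt, cr$c_pct),
    ph = runif_range(nt, cr$ph),
    p_m3 = runif_range(nt, cr$p_m3),
    k_m3 = runif_range(nt, cr$k_m3),
    ca_m3 = runif_range(nt, cr$ca_m3),
    mg_m3 = runif_range(nt, cr$mg_m3),
    al_m3 = runif_range(nt, cr$al_m3),
    density = runif_range(nt, cr$density),
    season_length = season_length,
    planting_date = planting,
    harvest_date = harvest,
    maturity_class = maturity,
    stringsAsFactors = FALSE)
  trial_cov <- cbind(trial_cov, mem)

  # dose design per trial
  design <- vector("list", nt)
  for (i in seq_len(nt)) {
    type <- config$trial_type[i]
    if (type == "factorial") {
      levels3 <- lapply(bounds, function(b) seq(0, b, length.out = 4))
      grid <- expand.grid(dose_N = levels3[["N"]], dose_P = levels3[["P"]],
                          dose_K = levels3[["K"]])
      design[[i]] <- grid[sample(nrow(grid), ntr), , drop = FALSE]
    } else {
      tested <- seq(0, bounds[[type]], length.out = ntr)
      grower <- stats::runif(2, 0.3, 0.5)
      others <- setdiff(c("N", "P", "K"), type)
      d <- data.frame(dose_N = 0, dose_P = 0, dose_K = 0)[rep(1, ntr), ]
      d[[paste0("dose_", type)]] <- tested
      d[[paste0("dose_", others[1])]] <- round(grower[1] * bounds[[others[1]]])
      d[[paste0("dose_", others[2])]] <- round(grower[2] * bounds[[others[2]]])
      design[[i]] <- d
    }
    rownames(design[[i]]) <- NULL
  }

  # block effects on the asymptote
  block_effects <- data.frame(
    trial = rep(seq_len(nt), each = nb),
    block = rep(seq_len(nb), nt),
    u = stats::rnorm(nt * nb, 0, config$block_sd))

  # plot-level table: all treatments in every block (RCBD)
  rows <- vector("list", nt)
  for (i in seq_len(nt)) {
    d <- design[[i]][rep(seq_len(ntr), times = nb), , drop = FALSE]
    rows[[i]] <- data.frame(
      trial = i,
      block = rep(seq_len(nb), each = ntr),
      treatment = rep(seq_len(ntr), times = nb),
      d, row.names = NULL)
  }
  plots <- do.call(rbind, rows)
  plots <- merge(plots, trial_cov, by = "trial", sort = FALSE)
  plots <- plots[order(plots$trial, plots$block, plots$treatment), ]
  rownames(plots) <- NULL
  plots$plot_id <- sprintf("T%02d_B%d_P%d", plots$trial, plots$block,
                           plots$treatment)
  plots$site_id <- plots$trial

  # yields from the Mitscherlich surface + block effect + noise
  f <- mitscherlich_surface(1, config$true_R, config$true_E,
                            plots[, c("dose_N", "dose_P", "dose_K")])
  u <- block_effects$u[match(paste(plots$trial, plots$block),
                             paste(block_effects$trial, block_effects$block))]
  A_row <- config$true_A +
    config$cov_A[["density"]] * (plots$density - 36000) / 10000 +
    config$cov_A[["ph"]] * (plots$ph - 5.7)
  noise <- stats::rnorm(nrow(plots), 0, config$noise_sd)
  plots$yield <- pmax(0, (A_row + u) * f + noise)

  # tuber-size balances: density drives [S | M]; N dose shifts [M,S | L]
  size_coef <- list(msl = c(intercept = -0.3, dose_N = 0.004, dens = -0.4),
                    sm = c(intercept = 0.6, dose_N = 0.001, dens = -0.6))
  dens_z <- (plots$density - 36000) / 10000
  qsd <- config$quality_noise_sd
  b_msl <- size_coef$msl["intercept"] + size_coef$msl["dose_N"] * plots$dose_N +
    size_coef$msl["dens"] * dens_z + stats::rnorm(nrow(plots), 0, qsd)
  b_sm <- size_coef$sm["intercept"] + size_coef$sm["dose_N"] * plots$dose_N +
    size_coef$sm["dens"] * dens_z + stats::rnorm(nrow(plots), 0, qsd)
  fr <- ilr_inverse(cbind(b_msl, b_sm), potato_balance_schemes()$tuber_size)
  plots$frac_S <- fr[, "S"]; plots$frac_M <- fr[, "M"]; plots$frac_L <- fr[, "L"]
  plots$censored_L <- FALSE

  # specific gravity: weak dose effects, clipped to the physical range
  sg_coef <- c(intercept = 1.082, dose_N = -3e-5, dose_P = 1.5e-5)
  sg <- sg_coef["intercept"] + sg_coef["dose_N"] * plots$dose_N +
    sg_coef["dose_P"] * plots$dose_P +
    stats::rnorm(nrow(plots), 0, qsd / 50)
  plots$sg <- pmin(1.120, pmax(1.040, sg))

  weather <- generate_weather(trial_cov, config)

  truth <- list(params = list(A = config$true_A, R = config$true_R,
                              E = config$true_E, cov_A = config$cov_A),
                block_effects = block_effects,
                size_fraction_model = size_coef,
                sg_model = as.list(sg_coef),
                noise_sd = config$noise_sd, block_sd = config$block_sd)
  list(trials = plots, weather = weather, truth = truth)
}

# Daily weather per site: study season + 5 historical seasons.
# Rainfall: Bernoulli wet days (p = 0.45) with Gamma amounts; temperature:
# annual sinusoid (Quebec-like, ~20 C mid July) + noise.
generate_weather <- function(trial_cov, config) {
  out <- vector("list", nrow(trial_cov))
  for (i in seq_len(nrow(trial_cov))) {
    seasons <- vector("list", 6)
    for (s in 0:5) {
      w <- shift_years(c(trial_cov$planting_date[i],
                         trial_cov$harvest_date[i]), -s)
      dates <- seq(w[1], w[2], by = "day")
      n <- length(dates)
      wet <- stats::rbinom(n, 1, 0.45)
      rain <- round(wet * stats::rgamma(n, shape = 0.7, scale = 9), 1)
      doy <- as.integer(format(dates, "%j"))
      tmean <- round(5.5 - 14.5 * cos(2 * pi * (doy - 15) / 365) +
                       stats::rnorm(n, 0, 2.5), 1)
      seasons[[s + 1]] <- data.frame(site_id = trial_cov$trial[i],
                                     date = dates, rain_mm = rain,
                                     tmean_c = tmean)
    }
    out[[i]] <- do.call(rbind, seasons)
  }
  res <- do.call(rbind, out)
  res[order(res$site_id, res$date), ]
}

#' Censor the large-tuber fraction to zero in a random subset of plots
#'
#' Emulates plots where no large tubers were harvested (a frequent feature of
#' real trials): with probability `censor_prob` per row, sets the L fraction
#' to exact zero and re-closes S and M to sum to 1. Censored rows are marked
#' in the `censored_L` column.
#'
#' @param table Trial table with `frac_S`, `frac_M`, `frac_L` columns.
#' @param censor_prob Probability in \[0, 1\] that a row is censored.
#' @param seed Integer seed for the censoring draw.
#' @return The table with censored fractions.
#' @export
censor_large_fraction <- function(table, censor_prob, seed = 1) {
  stopifnot(all(c("frac_S", "frac_M", "frac_L") %in% names(table)))
  if (censor_prob < 0 || censor_prob > 1) {
    stop("censor_prob must lie in [0, 1]")
  }
  if (censor_prob == 0) return(table)
  set.seed(seed)
  hit <- stats::runif(nrow(table)) < censor_prob
  sm <- table$frac_S[hit] + table$frac_M[hit]
  table$frac_S[hit] <- table$frac_S[hit] / sm
  table$frac_M[hit] <- table$frac_M[hit] / sm
  table$frac_L[hit] <- 0
  table$censored_L <- table$censored_L | hit
  table
}

#' Write a generated dataset to plain-text files
#'
#' Writes `trials.csv`, `weather.csv` (ISO-8601 dates) and
#' `ground_truth.json` under `dir`.
#'
#' @param data Result of [generate_trials()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of file paths.
#' @export
write_trial_data <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, c("trials.csv", "weather.csv", "ground_truth.json"))
  utils::write.csv(data$trials, paths[1], row.names = FALSE)
  utils::write.csv(data$weather, paths[2], row.names = FALSE)
  jsonlite::write_json(data$truth, paths[3], auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(paths)
}
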