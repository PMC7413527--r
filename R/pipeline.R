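#' Configuration of an end-to-end pipeline run
#'
#' Bundles the stage toggles, generator settings, target and model choices,
#' split/tuning/optimization seeds, price model and dose-grid settings of a
#' reproducible run. All seeds are recorded in the run manifest; rerunning
#' an identical config reproduces all numeric outputs.
#'
#' @param generator A [generator_config()].
#' @param target Target variable: "yield", "bal_MSL", "bal_SM" or "sg".
#' @param families Model families to train (subset of knn, rf, nn, gp).
#' @param include_mitscherlich Also fit the Mitscherlich surface (only
#'   meaningful for the yield target).
#' @param train_fraction Block-level training share (default 0.7).
#' @param n_search_iter Random-search iterations per family.
#' @param n_posterior_samples Posterior draws for the GP dose distribution.
#' @param stages Character vector of stages to run, in order, among
#'   "generate", "preprocess", "fit", "evaluate", "optimize".
#' @param prices A [price_model()].
#' @param grid_n_points,grid_bounds Dose-grid settings (see [dose_grid()]).
#' @param seed_split,seed_tune,seed_optimize Stage seeds.
#' @return A `run_config` list.
#' @export
run_config <- function(generator = generator_config(),
                       target = "yield",
                       families = c("knn", "rf", "nn", "gp"),
                       include_mitscherlich = TRUE,
                       train_fraction = 0.7,
                       n_search_iter = 10,
                       n_posterior_samples = 1000,
                       stages = c("generate", "preprocess", "fit",
                                  "evaluate", "optimize"),
                       prices = price_model(),
                       grid_n_points = 1000,
                       grid_bounds = c(N = 250, P = 110, K = 208),
                       seed_split = 1, seed_tune = 2, seed_optimize = 3) {
  stopifnot(target %in% c("yield", "bal_MSL", "bal_SM", "sg"),
            all(families %in% c("knn", "rf", "nn", "gp")),
            all(stages %in% c("generate", "preprocess", "fit", "evaluate",
                              "optimize")))
  structure(list(generator = generator, target = target,
                 families = families,
                 include_mitscherlich = include_mitscherlich,
                 train_fraction = train_fraction,
                 n_search_iter = n_search_iter,
                 n_posterior_samples = n_posterior_samples,
                 stages = stages, prices = prices,
                 grid_n_points = grid_n_points, grid_bounds = grid_bounds,
                 seed_split = seed_split, seed_tune = seed_tune,
                 seed_optimize = seed_optimize),
            class = "run_config")
}

#' Execute a pipeline run
#'
#' Runs the requested stages (generate synthetic trials, preprocess into
#' the modelling frame and block-level split, fit the requested models,
#' evaluate them on the held-out blocks, optimize doses for a test site)
#' and writes every artifact plus a manifest (config hash, seeds, files,
#' timings) under `out_dir`.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory for the run artifacts.
#' @return Invisibly, a list with the in-memory artifacts (`data`, `frame`,
#'   `split`, `bundles`, `metrics`, `recommendation`, `manifest`).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  manifest <- list(config_hash = digest::digest(unclass(config)),
                   seeds = list(generator = config$generator$seed,
                                split = config$seed_split,
                                tune = config$seed_tune,
                                optimize = config$seed_optimize),
                   stages = list(), files = character(0))
  result <- list()
  note <- function(stage, files) {
    manifest$stages[[stage]] <<- list(
      elapsed_s = round(as.numeric(Sys.time() - t0, units = "secs"), 2))
    manifest$files <<- c(manifest$files, files)
  }

  if ("generate" %in% config$stages) {
    result$data <- generate_trials(config$generator)
    note("generate", basename(write_trial_data(result$data, out_dir)))
  }

  if ("preprocess" %in% config$stages) {
    if (is.null(result$data)) stop("preprocess stage needs generated data")
    result$frame <- make_model_frame(result$data$trials, result$data$weather)
    result$split <- split_blocks(result$frame, config$train_fraction,
                                 seed = config$seed_split)
    utils::write.csv(result$split$train, file.path(out_dir, "train.csv"),
                     row.names = FALSE)
    utils::write.csv(result$split$test, file.path(out_dir, "test.csv"),
                     row.names = FALSE)
    note("preprocess", c("train.csv", "test.csv"))
  }

  if ("fit" %in% config$stages) {
    if (is.null(result$split)) stop("fit stage needs the preprocess stage")
    result$bundles <- list()
    for (fam in config$families) {
      spec <- model_spec(fam, n_search_iter = config$n_search_iter,
                         seed = config$seed_tune)
      result$bundles[[fam]] <- train_response_model(
        result$split$train, config$target, spec)
    }
    if (config$include_mitscherlich && config$target == "yield") {
      result$mitscherlich <- fit_mitscherlich(result$split$train,
                                              response = "yield",
                                              group = "trial",
                                              seed = config$seed_tune)
    }
    note("fit", character(0))
  }

  if ("evaluate" %in% config$stages) {
    if (is.null(result$bundles)) stop("evaluate stage needs the fit stage")
    rows <- lapply(names(result$bundles), function(fam) {
      b <- result$bundles[[fam]]
      ztest <- apply_standardizer(b$standardizer, result$split$test)
      cbind(model = fam,
            evaluate(b$model, as.matrix(ztest[, b$features, drop = FALSE]),
                     result$split$test[[config$target]]))
    })
    if (!is.null(result$mitscherlich)) {
      m <- regression_metrics(result$split$test$yield,
                              predict_level0(result$mitscherlich,
                                             result$split$test))
      rows <- c(rows, list(data.frame(model = "mitscherlich", r2 = m$r2,
                                      mae = m$mae, rmse = m$rmse,
                                      n_test = nrow(result$split$test))))
    }
    result$metrics <- do.call(rbind, rows)
    utils::write.csv(result$metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
    note("evaluate", "metrics.csv")
  }

  if ("optimize" %in% config$stages) {
    if (is.null(result$bundles)) stop("optimize stage needs the fit stage")
    fam <- if ("gp" %in% names(result$bundles)) "gp" else
      names(result$bundles)[1]
    bundle <- result$bundles[[fam]]
    fixed_row <- result$split$test[1, , drop = FALSE]
    grid <- dose_grid(config$grid_n_points, config$grid_bounds,
                      seed = config$seed_optimize)
    rec <- if (config$target == "yield") {
      economic_optimum(bundle, fixed_row, grid, config$prices)
    } else {
      agronomic_optimum(bundle, fixed_row, grid)
    }
    if (fam == "gp") {
      rec_prob <- sample_optimal_doses(
        bundle, fixed_row, grid, n_samples = config$n_posterior_samples,
        mode = if (config$target == "yield") "economic" else "agronomic",
        prices = config$prices, seed = config$seed_optimize)
      rec$percentiles <- rec_prob$percentiles
      rec$per_sample_optima <- rec_prob$per_sample_optima
      rec$modal_bin <- rec_prob$modal_bin
      rec$mean_curve_optimum <- rec_prob$mean_curve_optimum
    }
    result$recommendation <- rec
    ox <- elemental_to_oxide(rec$optimum[["dose_P"]], rec$optimum[["dose_K"]])
    jsonlite::write_json(
      list(mode = rec$mode, model = fam, optimum = as.list(rec$optimum),
           oxide = ox, predicted = rec$predicted,
           objective_at_optimum = rec$objective_at_optimum,
           percentiles = if (!is.null(rec$percentiles))
             as.data.frame(rec$percentiles)),
      file.path(out_dir, "recommendation.json"),
      auto_unbox = TRUE, digits = NA)
    note("optimize", "recommendation.json")
  }

  manifest$files <- unique(manifest$files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  result$manifest <- manifest
  invisible(result)
}
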