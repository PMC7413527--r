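MATURITY_CLASSES <- c("early", "early_mid", "mid", "mid_late", "late")

#' Assemble the plot-level modelling frame
#'
#' Joins the plot table with per-site weather indices (PPT, SDI, T, GDD
#' averaged over the five seasons preceding the study season), computes the
#' ilr balance covariates (soil texture + carbon, soil-type drainage
#' gradient, the S(P, Al) and S(K, Ca, Mg) chemical simplexes with filler
#' value Fv = 1e6 mg kg-1 minus the measured parts), one-hot encodes the
#' maturity class, and derives the tuber-size balance targets \[M,S | L\] and
#' \[S | M\] from zero-imputed size fractions.
#'
#' @param trials Plot table as produced by [generate_trials()] (or a mapped
#'   external table with the same column dictionary).
#' @param weather Daily weather series with site_id, date, rain_mm, tmean_c.
#' @param n_seasons Historical seasons averaged for weather indices.
#' @param detection_limit Passed to [impute_size_zeros()].
#' @return Data frame carrying id columns (`trial`, `block`, `plot_id`,
#'   `trial_type`), predictor columns (attribute `"features"`) and target
#'   columns `yield`, `bal_MSL`, `bal_SM`, `sg`.
#' @export
make_model_frame <- function(trials, weather, n_seasons = 5,
                             detection_limit = 0.65) {
  schemes <- potato_balance_schemes()

  # weather indices per site
  idx_by_site <- lapply(split(seq_len(nrow(trials)), trials$site_id),
                        function(rows) {
    i <- rows[1]
    w <- weather[weather$site_id == trials$site_id[i], ]
    wi <- weather_indices(w, c(trials$planting_date[i],
                               trials$harvest_date[i]), n_seasons)
    data.frame(site_id = trials$site_id[i], T = wi$T, PPT = wi$PPT,
               SDI = wi$SDI, GDD = wi$GDD)
  })
  widx <- do.call(rbind, idx_by_site)

  out <- merge(trials, widx, by = "site_id", sort = FALSE)
  out <- out[order(out$trial, out$block, out$treatment), ]
  rownames(out) <- NULL

  # balances
  tex <- ilr_transform(cbind(sand = out$sand, silt = out$silt,
                             clay = out$clay, C = out$c_pct),
                       schemes$texture)
  colnames(tex) <- c("bal_texture_C", "bal_clay_sandsilt", "bal_silt_sand")
  fv_p <- 1e6 - (out$al_m3 + out$p_m3)
  chp <- ilr_transform(cbind(Fv = fv_p, Al = out$al_m3, P = out$p_m3),
                       schemes$chem_p)
  colnames(chp) <- c("bal_fv_alp", "bal_al_p")
  fv_k <- 1e6 - (out$k_m3 + out$ca_m3 + out$mg_m3)
  chk <- ilr_transform(cbind(Fv = fv_k, Mg = out$mg_m3, Ca = out$ca_m3,
                             K = out$k_m3), schemes$chem_k)
  colnames(chk) <- c("bal_fvmgca_k", "bal_fv_mgca", "bal_mg_ca")
  sty <- ilr_transform(cbind(loamy_gleyed = out$mem_loamy_gleyed,
                             sandy_gleyed = out$mem_sandy_gleyed,
                             podzolized = out$mem_podzolized),
                       schemes$soil_type)
  colnames(sty) <- c("bal_gley_podzol", "bal_loamy_sandy")

  # maturity one-hot; unseen classes map to all-zero with a warning
  unseen <- setdiff(unique(out$maturity_class), MATURITY_CLASSES)
  if (length(unseen)) {
    warning("unknown maturity class(es) ", paste(unseen, collapse = ", "),
            " encoded as all-zero")
  }
  mat <- vapply(MATURITY_CLASSES,
                function(cl) as.numeric(out$maturity_class == cl),
                numeric(nrow(out)))
  colnames(mat) <- paste0("mat_", MATURITY_CLASSES)

  # tuber-size balance targets from zero-imputed fractions
  fr <- impute_size_zeros(cbind(S = out$frac_S, M = out$frac_M,
                                L = out$frac_L), detection_limit)
  bt <- ilr_transform(fr, schemes$tuber_size)

  frame <- data.frame(
    trial = out$trial, block = out$block, plot_id = out$plot_id,
    trial_type = out$trial_type,
    dose_N = out$dose_N, dose_P = out$dose_P, dose_K = out$dose_K,
    density = out$density, season_length = out$season_length, ph = out$ph,
    T = out$T, PPT = out$PPT, SDI = out$SDI, GDD = out$GDD,
    tex, sty, chp, chk, mat,
    yield = out$yield, bal_MSL = bt[, 1], bal_SM = bt[, 2], sg = out$sg,
    stringsAsFactors = FALSE)
  attr(frame, "features") <- c(
    "dose_N", "dose_P", "dose_K", "density", "season_length", "ph",
    "T", "PPT", "SDI", "GDD", colnames(tex), colnames(sty), colnames(chp),
    colnames(chk), colnames(mat))
  attr(frame, "targets") <- c("yield", "bal_MSL", "bal_SM", "sg")
  frame
}

#' Feature column names of a model frame
#' @param frame Output of [make_model_frame()].
#' @return Character vector of predictor column names.
#' @export
feature_columns <- function(frame) attr(frame, "features")

#' Fit / apply a column standardizer (z-scoring with training statistics)
#'
#' Training-set means and standard deviations are stored and re-used
#' verbatim on any later table, so test rows never leak into the statistics.
#' Zero-variance columns are passed through unscaled with a warning.
#'
#' @param table Training data frame.
#' @param columns Columns to standardize.
#' @return `fit_standardizer`: a `standardizer` object; `apply_standardizer`:
#'   the table with standardized columns.
#' @export
fit_standardizer <- function(table, columns) {
  stopifnot(all(columns %in% names(table)))
  mu <- vapply(columns, function(cl) mean(table[[cl]]), numeric(1))
  sd_ <- vapply(columns, function(cl) stats::sd(table[[cl]]), numeric(1))
  zero_var <- !is.finite(sd_) | sd_ < 1e-12
  if (any(zero_var)) {
    warning("zero-variance column(s) left unscaled: ",
            paste(columns[zero_var], collapse = ", "))
    sd_[zero_var] <- 1
    mu[zero_var] <- 0
  }
  structure(list(columns = columns, mean = mu, sd = sd_),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std A `standardizer`.
#' @export
apply_standardizer <- function(std, table) {
  stopifnot(inherits(std, "standardizer"))
  for (cl in std$columns) {
    table[[cl]] <- (table[[cl]] - std$mean[[cl]]) / std$sd[[cl]]
  }
  table
}

#' Remove multivariate outliers by univariate z-score
#'
#' Drops every row whose value on any monitored column lies more than
#' `threshold` standard deviations from that column's mean (statistics from
#' the supplied table itself). Zero-variance columns are skipped with a
#' warning. By convention this cleaning is applied to the specific-gravity
#' modelling dataset only.
#'
#' @param table Data frame.
#' @param columns Numeric columns to monitor.
#' @param threshold z-score threshold (default 3).
#' @return The kept rows, with attribute `n_dropped`.
#' @export
remove_outliers_zscore <- function(table, columns, threshold = 3) {
  stopifnot(all(columns %in% names(table)), threshold > 0)
  keep <- rep(TRUE, nrow(table))
  for (cl in columns) {
    v <- table[[cl]]
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) {
      warning("zero-variance column skipped: ", cl)
      next
    }
    keep <- keep & abs(v - mean(v)) / s <= threshold
  }
  out <- table[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Block-level train/test split stratified by trial type
#'
#' Whole blocks (trial x block combinations) are assigned to either set, so
#' no block contributes rows to both; assignment is stratified within trial
#' types (N, P, K, factorial, ...) and targets a 70/30 row split by default.
#' A stratum with fewer than 2 blocks goes wholly to training with a
#' warning.
#'
#' @param table Data frame with `trial`, `block` and `trial_type` columns.
#' @param train_fraction Target share of rows in training (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `test` data frames; block ids of each side
#'   are recorded in attributes `train_blocks` / `test_blocks`.
#' @export
split_blocks <- function(table, train_fraction = 0.7, seed = 1) {
  stopifnot(all(c("trial", "block", "trial_type") %in% names(table)),
            train_fraction > 0, train_fraction < 1)
  set.seed(seed)
  block_id <- paste(table$trial, table$block, sep = ":")
  train_ids <- character(0)
  test_ids <- character(0)
  for (stratum in unique(table$trial_type)) {
    in_str <- table$trial_type == stratum
    ids <- unique(block_id[in_str])
    if (length(ids) < 2) {
      warning("stratum '", stratum, "' has < 2 blocks; assigned to training")
      train_ids <- c(train_ids, ids)
      next
    }
    ids <- sample(ids)
    sizes <- vapply(ids, function(b) sum(block_id == b), numeric(1))
    share <- cumsum(sizes) / sum(sizes)
    cut <- which.min(abs(share[seq_len(length(ids) - 1)] - train_fraction))
    train_ids <- c(train_ids, ids[seq_len(cut)])
    test_ids <- c(test_ids, ids[-seq_len(cut)])
  }
  train <- table[block_id %in% train_ids, , drop = FALSE]
  test <- table[block_id %in% test_ids, , drop = FALSE]
  attr(train, "features") <- attr(table, "features")
  attr(test, "features") <- attr(table, "features")
  structure(list(train = train, test = test),
            train_blocks = train_ids, test_blocks = test_ids)
}

#' Feature importance by extremely randomized trees
#'
#' Fits an ensemble of extremely randomized regression trees on the training
#' rows and scores each feature by its total impurity (variance) reduction,
#' normalized to sum to 1 and sorted in decreasing order. Features scoring
#' below `flag_below` are flagged for removal in the `"flagged"` attribute.
#'
#' @param train Data frame (training rows only).
#' @param target Target column name.
#' @param features Feature column names (default: the `"features"`
#'   attribute).
#' @param n_trees Ensemble size (default 100).
#' @param flag_below Score below which a feature is flagged (default 0.005).
#' @param seed Integer seed.
#' @return Named numeric vector of scores (sums to 1, decreasing).
#' @export
rank_features <- function(train, target, features = attr(train, "features"),
                          n_trees = 100, flag_below = 0.005, seed = 1) {
  stopifnot(!is.null(features), target %in% names(train))
  y <- train[[target]]
  if (stats::sd(y) < 1e-12) stop("constant target: importance undefined")
  X <- as.matrix(train[, features, drop = FALSE])
  forest <- fit_forest(X, y, n_trees = n_trees, method = "extra", seed = seed)
  imp <- forest$importance
  if (sum(imp) <= 0) imp[] <- 1 / length(imp)
  scores <- sort(imp / sum(imp), decreasing = TRUE)
  attr(scores, "flagged") <- names(scores)[scores < flag_below]
  scores
}
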