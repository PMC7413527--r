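#' Tri-variate Mitscherlich dose-response surface
#'
#' \deqn{Y = A \prod_{X \in \{N,P,K\}} \left(1 - e^{-R_X (E_X + dose_X)}\right)}
#' where A is the asymptote (Mg ha-1), R_X the rate (ha kg-1) and E_X the
#' fertilizer-equivalent environmental supply (kg ha-1) of nutrient X. The
#' surface is bounded above by A and non-decreasing in every dose.
#'
#' @param A Asymptote, scalar or vector of length nrow(dose).
#' @param R Named vector c(N=, P=, K=) of positive rates.
#' @param E Named vector c(N=, P=, K=) of non-negative environment supplies.
#' @param dose Data frame or matrix with columns dose_N, dose_P, dose_K
#'   (kg ha-1), or a length-3 vector.
#' @return Predicted response, same length as rows of `dose`.
#' @export
mitscherlich_surface <- function(A, R, E, dose) {
  if (is.null(dim(dose))) dose <- matrix(dose, nrow = 1,
                                         dimnames = list(NULL, c("dose_N", "dose_P", "dose_K")))
  dose <- as.matrix(dose)
  if (any(A <= 0) || any(R[c("N", "P", "K")] <= 0) ||
      any(E[c("N", "P", "K")] < 0)) {
    stop("need A > 0, R > 0 and E >= 0")
  }
  f <- (1 - exp(-R[["N"]] * (E[["N"]] + dose[, "dose_N"]))) *
    (1 - exp(-R[["P"]] * (E[["P"]] + dose[, "dose_P"]))) *
    (1 - exp(-R[["K"]] * (E[["K"]] + dose[, "dose_K"])))
  unname(A * f)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(x)))
softplus_inv <- function(y) ifelse(y > 30, y, log(expm1(y)))

# unpack the parameter vector into evaluated (A, R, E) given model matrices
mits_eval_params <- function(theta, mm) {
  idx <- attr(mm, "index")
  list(A = exp(drop(mm$A %*% theta[idx$A])),
       R = list(N = softplus(drop(mm$RN %*% theta[idx$RN])),
                P = softplus(drop(mm$RP %*% theta[idx$RP])),
                K = softplus(drop(mm$RK %*% theta[idx$RK]))),
       E = list(N = softplus(drop(mm$EN %*% theta[idx$EN])),
                P = softplus(drop(mm$EP %*% theta[idx$EP])),
                K = softplus(drop(mm$EK %*% theta[idx$EK]))))
}

mits_model_matrices <- function(data, covariates) {
  n <- nrow(data)
  mk <- function(cols) {
    if (length(cols) == 0) return(matrix(1, n, 1))
    cbind(1, as.matrix(data[, cols, drop = FALSE]))
  }
  mm <- list(A = mk(covariates$A),
             RN = mk(covariates$R), RP = mk(covariates$R), RK = mk(covariates$R),
             EN = mk(covariates$E), EP = mk(covariates$E), EK = mk(covariates$E))
  sizes <- vapply(mm, ncol, integer(1))
  ends <- cumsum(sizes)
  starts <- c(1, utils::head(ends, -1) + 1)
  attr(mm, "index") <- stats::setNames(
    Map(seq, starts, ends), names(mm))
  attr(mm, "n_par") <- sum(sizes)
  mm
}

# mean response at theta with random effects at zero
mits_mean <- function(theta, mm, dose) {
  p <- mits_eval_params(theta, mm)
  fN <- 1 - exp(-p$R$N * (p$E$N + dose[, "dose_N"]))
  fP <- 1 - exp(-p$R$P * (p$E$P + dose[, "dose_P"]))
  fK <- 1 - exp(-p$R$K * (p$E$K + dose[, "dose_K"]))
  list(mu = p$A * fN * fP * fK, f = fN * fP * fK, A = p$A)
}

# negative Gaussian marginal log-likelihood with a random intercept u_g on A:
# within group g, y = (A + u_g) f + e, so Sigma_g = su^2 f f' + s2 I and the
# rank-one Woodbury/determinant identities give an exact evaluation.
mits_nll <- function(theta_full, mm, dose, y, group) {
  k <- attr(mm, "n_par")
  theta <- theta_full[seq_len(k)]
  su2 <- exp(theta_full[k + 1])^2
  s2 <- exp(theta_full[k + 2])^2
  m <- mits_mean(theta, mm, dose)
  r <- y - m$mu
  nll <- 0
  for (g in unique(group)) {
    i <- which(group == g)
    fg <- m$f[i]; rg <- r[i]; ng <- length(i)
    denom <- s2 + su2 * sum(fg^2)
    quad <- (sum(rg^2) - su2 * sum(fg * rg)^2 / denom) / s2
    logdet <- (ng - 1) * log(s2) + log(denom)
    nll <- nll + 0.5 * (ng * log(2 * pi) + logdet + quad)
  }
  if (!is.finite(nll)) nll <- 1e10
  nll
}

#' Fit the hierarchical Mitscherlich response surface
#'
#' The first-level parameters A, E_N, E_P, E_K, R_N, R_P, R_K are linear
#' forms in (optional) covariates, mapped through positivity links
#' (A through exp, E and R through softplus), with a Gaussian random
#' intercept on the asymptote at the grouping level (trial or block). The
#' fixed effects are first estimated by multi-start nonlinear least squares
#' (BFGS); when the residual variance is non-degenerate the variance
#' components are then estimated by exact Gaussian marginal maximum
#' likelihood (the random intercept enters A linearly, so each group
#' covariance is a rank-one update and the marginal likelihood is closed
#' form).
#'
#' @param data Data frame with columns `dose_N`, `dose_P`, `dose_K` (raw
#'   kg ha-1), the response and the grouping id, plus any covariate columns.
#' @param response Name of the response column (default "yield").
#' @param group Name of the grouping column for the random intercept
#'   (default "trial").
#' @param covariates List with elements `A`, `E`, `R`: character vectors of
#'   covariate column names entering each linear form (default: intercepts
#'   only).
#' @param n_starts Number of seeded multi-start restarts (default 5).
#' @param seed Seed for the restart jitter.
#' @return Object of class `mitscherlich_fit` with elements `params`
#'   (evaluated A, R, E at the average covariate row for intercept-only
#'   fits), `theta`, `sigma_group`, `sigma_resid`, `diagnostics` and the
#'   link/model-matrix metadata needed for prediction.
#' @export
fit_mitscherlich <- function(data, response = "yield", group = "trial",
                             covariates = list(A = character(),
                                               E = character(),
                                               R = character()),
                             n_starts = 5, seed = 1) {
  stopifnot(all(c("dose_N", "dose_P", "dose_K", response, group) %in%
                  names(data)))
  dose <- as.matrix(data[, c("dose_N", "dose_P", "dose_K")])
  y <- data[[response]]
  grp <- data[[group]]
  if (length(unique(grp)) < 2) stop("need at least 2 groups")
  covariates <- utils::modifyList(
    list(A = character(), E = character(), R = character()), covariates)
  mm <- mits_model_matrices(data, covariates)
  k <- attr(mm, "n_par")
  idx <- attr(mm, "index")

  # identifiability: a nutrient whose dose never varies carries no
  # information about its E and R
  no_gradient <- c("N", "P", "K")[apply(dose, 2, function(d) {
    diff(range(d)) < 1e-9
  })]

  sse <- function(theta) {
    m <- mits_mean(theta, mm, dose)
    v <- sum((y - m$mu)^2)
    if (!is.finite(v)) 1e12 else v
  }
  init_base <- numeric(k)
  init_base[idx$A[1]] <- log(max(y) * 1.05 + 1e-6)
  for (nm in c("RN", "RP", "RK")) init_base[idx[[nm]][1]] <- softplus_inv(0.02)
  for (nm in c("EN", "EP", "EK")) init_base[idx[[nm]][1]] <- softplus_inv(50)

  # box bounds on the intercepts keep the optimizer off the degenerate
  # ridge A -> Inf, R -> 0 (the asymptote of a diminishing-returns yield
  # surface cannot plausibly exceed a few times the best observed yield)
  lower <- rep(-Inf, k); upper <- rep(Inf, k)
  lower[idx$A[1]] <- log(max(y) * 0.5); upper[idx$A[1]] <- log(max(y) * 4)
  for (nm in c("RN", "RP", "RK")) {
    lower[idx[[nm]][1]] <- softplus_inv(1e-4)
    upper[idx[[nm]][1]] <- softplus_inv(0.5)
  }
  for (nm in c("EN", "EP", "EK")) {
    lower[idx[[nm]][1]] <- softplus_inv(1e-6)
    upper[idx[[nm]][1]] <- softplus_inv(800)
  }

  set.seed(seed)
  best <- NULL
  for (s in seq_len(n_starts)) {
    init <- init_base
    if (s > 1) init <- init + stats::rnorm(k, 0, 0.5)
    init <- pmin(pmax(init, lower + 1e-6), upper - 1e-6)
    fit <- try(stats::optim(init, sse, method = "L-BFGS-B",
                            lower = lower, upper = upper,
                            control = list(maxit = 500, factr = 1e4)),
               silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all nonlinear least-squares starts failed")
  theta <- best$par
  n <- length(y)
  resid_var <- best$value / n

  sigma_group <- 0
  sigma_resid <- sqrt(resid_var)
  ml_conv <- NA
  if (resid_var > 1e-8) {
    start_full <- c(theta, log(max(sigma_resid / 2, 1e-3)),
                    log(max(sigma_resid, 1e-3)))
    lower_full <- c(lower, log(1e-4), log(1e-4))
    upper_full <- c(upper, log(100), log(100))
    mlfit <- try(stats::optim(start_full, mits_nll, mm = mm, dose = dose,
                              y = y, group = grp, method = "L-BFGS-B",
                              lower = lower_full, upper = upper_full,
                              control = list(maxit = 500, factr = 1e5)),
                 silent = TRUE)
    if (!inherits(mlfit, "try-error") && is.finite(mlfit$value)) {
      theta <- mlfit$par[seq_len(k)]
      sigma_group <- exp(mlfit$par[k + 1])
      sigma_resid <- exp(mlfit$par[k + 2])
      ml_conv <- mlfit$convergence
    }
  }

  p <- mits_eval_params(theta, mm)
  params <- list(A = mean(p$A),
                 R = c(N = mean(p$R$N), P = mean(p$R$P), K = mean(p$R$K)),
                 E = c(N = mean(p$E$N), P = mean(p$E$P), K = mean(p$E$K)))
  structure(list(theta = theta, params = params,
                 sigma_group = sigma_group, sigma_resid = sigma_resid,
                 covariates = covariates, response = response, group = group,
                 diagnostics = list(sse = best$value,
                                    nls_convergence = best$convergence,
                                    ml_convergence = ml_conv,
                                    unidentified = no_gradient,
                                    n = n)),
            class = "mitscherlich_fit")
}

#' @export
print.mitscherlich_fit <- function(x, ...) {
  cat("Mitscherlich surface fit (n =", x$diagnostics$n, ")\n")
  cat("  A =", format(x$params$A, digits = 4),
      " sigma_group =", format(x$sigma_group, digits = 3),
      " sigma_resid =", format(x$sigma_resid, digits = 3), "\n")
  cat("  R:", paste(names(x$params$R),
                    format(x$params$R, digits = 4), collapse = "  "), "\n")
  cat("  E:", paste(names(x$params$E),
                    format(x$params$E, digits = 4), collapse = "  "), "\n")
  if (length(x$diagnostics$unidentified)) {
    cat("  warning: no dose gradient for",
        paste(x$diagnostics$unidentified, collapse = ", "),
        "- E/R unidentifiable for these nutrients\n")
  }
  invisible(x)
}

#' Predict from a Mitscherlich fit with random effects at zero (level 0)
#'
#' Evaluates the fitted surface row-wise with the group random intercept set
#' to zero, so predictions depend only on doses and covariates, never on the
#' group identity.
#'
#' @param object A `mitscherlich_fit`.
#' @param newdata Data frame with dose columns and any covariates used.
#' @param ... Unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.mitscherlich_fit <- function(object, newdata, ...) {
  dose <- as.matrix(newdata[, c("dose_N", "dose_P", "dose_K")])
  mm <- mits_model_matrices(newdata, object$covariates)
  mits_mean(object$theta, mm, dose)$mu
}

#' @rdname predict.mitscherlich_fit
#' @param fit A `mitscherlich_fit`.
#' @export
predict_level0 <- function(fit, newdata) predict(fit, newdata)

#' Serialize / read Mitscherlich parameters as JSON
#'
#' @param fit A `mitscherlich_fit`.
#' @param path Output file path.
#' @return `write_mitscherlich` invisibly returns `path`;
#'   `read_mitscherlich` returns the parameter list.
#' @export
write_mitscherlich <- function(fit, path) {
  jsonlite::write_json(
    list(theta = fit$theta, params = fit$params,
         sigma_group = fit$sigma_group, sigma_resid = fit$sigma_resid,
         covariates = fit$covariates, links = list(A = "exp", E = "softplus",
                                                   R = "softplus")),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_mitscherlich
#' @export
read_mitscherlich <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)
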