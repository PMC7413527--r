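#' Train a response model bundled with its preprocessing
#'
#' Fits the standardizer on the training rows only, tunes the requested
#' model family by random-search cross-validation on the standardized
#' features, and returns a bundle whose `predict` method accepts raw
#' (unstandardized) rows — the bundle re-applies the training statistics, so
#' overwriting dose columns on a raw row and predicting is equivalent to
#' predicting on a freshly standardized table.
#'
#' @param train Training rows of a model frame ([make_model_frame()]).
#' @param target Target column ("yield", "bal_MSL", "bal_SM" or "sg").
#' @param spec A [model_spec()].
#' @param features Feature column names (default: the frame's `"features"`
#'   attribute).
#' @return A `response_bundle` with elements `model`, `standardizer`,
#'   `features`, `target`.
#' @export
train_response_model <- function(train, target, spec,
                                 features = attr(train, "features")) {
  stopifnot(!is.null(features), target %in% names(train))
  std <- fit_standardizer(train, features)
  ztrain <- apply_standardizer(std, train)
  model <- tune_fit(spec, as.matrix(ztrain[, features, drop = FALSE]),
                    train[[target]])
  structure(list(model = model, standardizer = std, features = features,
                 target = target, family = spec$family),
            class = "response_bundle")
}

#' @export
predict.response_bundle <- function(object, newdata, ...) {
  z <- apply_standardizer(object$standardizer, newdata)
  predict(object$model, as.matrix(z[, object$features, drop = FALSE]))
}

#' @export
print.response_bundle <- function(x, ...) {
  hp <- attr(x$model, "hyperparameters")
  cat("Response model bundle:", x$family, "->", x$target, "\n")
  if (!is.null(hp)) {
    cat("  tuned:", paste(names(hp), unlist(hp), sep = "=", collapse = ", "),
        "\n")
  }
  invisible(x)
}

# uniform prediction interface over raw rows: plain functions,
# bundles, Mitscherlich fits, or any model with a predict method
predict_rows <- function(model, newdata) {
  if (is.function(model)) return(model(newdata))
  predict(model, newdata)
}
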