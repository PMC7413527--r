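# Regression-tree ensemble engine (CART-style forests and extremely
# randomized trees). Pure R: trees are grown on index subsets with
# vectorized split search; nodes live in parallel arrays.

# exhaustive best split for one feature: O(n log n) via sorted cumulative sums
split_cart <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(ys)
  cs <- cumsum(ys); css <- cumsum(ys * ys)
  i <- seq_len(n - 1)
  valid <- xs[i] < xs[i + 1]
  if (!any(valid)) return(NULL)
  sse_l <- css[i] - cs[i]^2 / i
  sse_r <- (css[n] - css[i]) - (cs[n] - cs[i])^2 / (n - i)
  tot <- sse_l + sse_r
  tot[!valid] <- Inf
  b <- which.min(tot)
  list(threshold = (xs[b] + xs[b + 1]) / 2, sse = tot[b])
}

# extremely randomized split: one uniform threshold in the feature's range
split_extra <- function(x, y) {
  lo <- min(x); hi <- max(x)
  if (hi <= lo) return(NULL)
  thr <- stats::runif(1, lo, hi)
  left <- x <= thr
  nl <- sum(left); nr <- length(y) - nl
  if (nl == 0 || nr == 0) return(NULL)
  yl <- y[left]; yr <- y[!left]
  sse <- sum(yl^2) - sum(yl)^2 / nl + sum(yr^2) - sum(yr)^2 / nr
  list(threshold = thr, sse = sse)
}

grow_tree <- function(X, y, mtry, min_split, max_depth, splitter) {
  p <- ncol(X)
  env <- new.env()
  env$feature <- integer(0); env$threshold <- numeric(0)
  env$left <- integer(0); env$right <- integer(0); env$value <- numeric(0)
  env$importance <- numeric(p)

  new_node <- function() {
    id <- length(env$feature) + 1L
    env$feature[id] <- 0L; env$threshold[id] <- NA_real_
    env$left[id] <- 0L; env$right[id] <- 0L; env$value[id] <- NA_real_
    id
  }

  build <- function(idx, depth) {
    id <- new_node()
    yi <- y[idx]
    n <- length(idx)
    node_sse <- sum(yi^2) - sum(yi)^2 / n
    if (n < min_split || depth >= max_depth || node_sse < 1e-12) {
      env$value[id] <- mean(yi)
      return(id)
    }
    feats <- if (mtry < p) sample.int(p, mtry) else seq_len(p)
    best <- NULL; best_f <- 0L
    for (f in feats) {
      sp <- splitter(X[idx, f], yi)
      if (!is.null(sp) && (is.null(best) || sp$sse < best$sse)) {
        best <- sp; best_f <- f
      }
    }
    if (is.null(best) || best$sse >= node_sse - 1e-12) {
      env$value[id] <- mean(yi)
      return(id)
    }
    env$importance[best_f] <- env$importance[best_f] + (node_sse - best$sse)
    go_left <- X[idx, best_f] <= best$threshold
    env$feature[id] <- best_f
    env$threshold[id] <- best$threshold
    env$left[id] <- build(idx[go_left], depth + 1L)
    env$right[id] <- build(idx[!go_left], depth + 1L)
    id
  }
  build(seq_len(nrow(X)), 0L)
  list(feature = env$feature, threshold = env$threshold, left = env$left,
       right = env$right, value = env$value, importance = env$importance)
}

predict_tree <- function(tree, X) {
  cur <- rep(1L, nrow(X))
  repeat {
    internal <- tree$feature[cur] > 0L
    if (!any(internal)) break
    rows <- which(internal)
    nodes <- cur[rows]
    xv <- X[cbind(rows, tree$feature[nodes])]
    cur[rows] <- ifelse(xv <= tree$threshold[nodes],
                        tree$left[nodes], tree$right[nodes])
  }
  tree$value[cur]
}

fit_forest <- function(X, y, n_trees = 100, mtry = NULL,
                       min_split = 5, max_depth = 25,
                       method = c("cart", "extra"), bootstrap = NULL,
                       seed = NULL) {
  method <- match.arg(method)
  X <- as.matrix(X)
  p <- ncol(X)
  if (is.null(mtry)) {
    mtry <- if (method == "cart") max(1L, floor(p / 3)) else p
  }
  if (is.null(bootstrap)) bootstrap <- method == "cart"
  if (!is.null(seed)) set.seed(seed)
  splitter <- if (method == "cart") split_cart else split_extra
  trees <- vector("list", n_trees)
  imp <- numeric(p)
  n <- nrow(X)
  for (t in seq_len(n_trees)) {
    idx <- if (bootstrap) sample.int(n, n, replace = TRUE) else seq_len(n)
    tr <- grow_tree(X[idx, , drop = FALSE], y[idx], mtry, min_split,
                    max_depth, splitter)
    imp <- imp + tr$importance
    trees[[t]] <- tr
  }
  names(imp) <- colnames(X)
  structure(list(trees = trees, importance = imp, mtry = mtry,
                 method = method, columns = colnames(X)),
            class = "npk_forest")
}

#' @export
predict.npk_forest <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (!is.null(object$columns)) X <- X[, object$columns, drop = FALSE]
  preds <- vapply(object$trees, function(tr) predict_tree(tr, X),
                  numeric(nrow(X)))
  if (is.null(dim(preds))) preds <- matrix(preds, nrow = 1)
  rowMeans(preds)
}
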