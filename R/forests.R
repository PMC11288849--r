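#' Best single split of a regression-tree node
#'
#' Exhaustive search over the candidate features and all midpoints between
#' consecutive distinct feature values for the split minimizing
#' \eqn{RSS(R_1) + RSS(R_2)} with regions \eqn{R_1 = \{x_j < s\}},
#' \eqn{R_2 = \{x_j \ge s\}}. Ties are broken by lowest feature index, then
#' smallest split value.
#'
#' @param X numeric feature matrix (rows = observations).
#' @param y numeric response.
#' @param features candidate feature indices (default: all).
#' @return `list(feature, split, rss)` or `NULL` when no split improves on
#'   the unsplit node (constant response or constant features).
#' @export
best_split <- function(X, y, features = seq_len(ncol(X))) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y))
  if (nrow(X) < 2 || length(unique(y)) < 2) return(NULL)
  res <- .cpp_best_split(X, as.numeric(y), as.integer(features))
  if (!res$found) return(NULL)
  list(feature = res$feature, split = res$split, rss = res$rss)
}

#' Grow a single unpruned regression tree
#'
#' Recursive binary splitting with a fresh draw of `mtry` candidate features
#' at every node; a node is split while it holds at least `2 * min_node`
#' observations and a gainful split exists. Leaves keep both their mean and
#' their training-observation lists, so one tree serves both mean and
#' conditional-distribution prediction.
#'
#' @param X numeric feature matrix.
#' @param y numeric response.
#' @param min_node minimum node size eligible for further splitting is
#'   `2 * min_node` (default `min_node = 5`).
#' @param mtry candidate features per node (default: all).
#' @param seed optional RNG seed.
#' @return a `forest_model` containing the single tree.
#' @export
grow_tree <- function(X, y, min_node = 5, mtry = ncol(X), seed = NULL) {
  fit_rf(X, y, n_trees = 1, mtry = mtry, min_node = min_node, seed = seed,
         bootstrap = FALSE)
}

#' Fit a random forest (mean mode) or quantile regression forest
#'
#' Trees are grown to maximum size without pruning on bootstrap resamples of
#' the training data, with `mtry` features sampled per node. Defaults follow
#' the usual regression-forest settings: 500 trees and
#' `mtry = ceiling(v/3)` over `v` features. The returned model predicts
#' means ([predict.forest_model()]); because leaves retain their training
#' observations, the same fitted forest also yields conditional
#' distributions and quantiles ([qrf_weights()], [predict_qrf()]) — the
#' quantile forest differs only in how predictions are read off.
#'
#' @param X numeric feature matrix (rows named by individual ids if
#'   available).
#' @param y numeric response.
#' @param n_trees number of trees (default 500).
#' @param mtry features sampled per node (default `ceiling(ncol(X)/3)`).
#' @param min_node nodes with fewer than `2 * min_node` observations become
#'   leaves (default 5).
#' @param seed optional RNG seed making the forest reproducible.
#' @param bootstrap set `FALSE` to grow every tree on the full sample (test
#'   hook; single-tree reduction).
#' @return an object of class `forest_model`.
#' @export
fit_rf <- function(X, y, n_trees = 500, mtry = ceiling(ncol(X) / 3),
                   min_node = 5, seed = NULL, bootstrap = TRUE) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  stopifnot(n == length(y), ncol(X) >= 1)
  if (n_trees < 1) stop("n_trees must be >= 1")
  if (min_node < 1) stop("min_node must be >= 1")
  mtry <- max(1L, min(as.integer(mtry), ncol(X)))
  if (!is.null(seed)) set.seed(seed)
  boot <- if (bootstrap)
    matrix(sample.int(n, n * n_trees, replace = TRUE), n, n_trees)
  else matrix(rep(seq_len(n), n_trees), n, n_trees)
  seeds <- sample.int(.Machine$integer.max - 1L, n_trees)
  trees <- .cpp_fit_forest(X, as.numeric(y), boot, mtry, as.integer(min_node),
                           seeds)
  structure(list(trees = trees, n_trees = n_trees, mtry = mtry,
                 min_node = min_node, y = as.numeric(y),
                 ids = rownames(X), p = ncol(X), bootstrap = bootstrap),
            class = "forest_model")
}

#' @export
print.forest_model <- function(x, ...) {
  cat("regression forest:", x$n_trees, "trees, mtry =", x$mtry,
      ", min_node =", x$min_node, ", n =", length(x$y), "\n")
  invisible(x)
}

.check_X <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  storage.mode(Xnew) <- "double"
  if (ncol(Xnew) != model$p)
    stop("query has ", ncol(Xnew), " features; model was trained on ",
         model$p)
  Xnew
}

#' Mean prediction from a fitted forest
#' @param object a `forest_model`.
#' @param Xnew feature matrix of query rows.
#' @param ... unused.
#' @return numeric vector: per query row, the average over trees of leaf
#'   means.
#' @export
predict.forest_model <- function(object, Xnew, ...) {
  Xnew <- .check_X(object, Xnew)
  out <- .cpp_forest_predict(object$trees, Xnew)
  names(out) <- rownames(Xnew)
  out
}

#' Conditional-distribution weights of a quantile regression forest
#'
#' For each query row, every training observation in the query's leaf of
#' tree `t` receives weight `1 / (leaf size * n_trees)`, counting bootstrap
#' multiplicities; weights are accumulated over trees and sum to 1 per
#' query.
#'
#' @param model a `forest_model`.
#' @param Xnew feature matrix of query rows (a single row may be passed as a
#'   vector).
#' @return matrix `nrow(Xnew)` by `n_train` of non-negative weights with
#'   unit row sums.
#' @export
qrf_weights <- function(model, Xnew) {
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  Xnew <- .check_X(model, Xnew)
  Wt <- .cpp_forest_weights(model$trees, Xnew, length(model$y))
  dimnames(Wt) <- list(rownames(Xnew), model$ids)
  Wt
}

#' Conditional-quantile prediction from a quantile regression forest
#'
#' Builds the weighted empirical conditional distribution
#' \eqn{\hat F(y | x) = \sum_i w_i(x) 1\{Y_i \le y\}} from [qrf_weights()]
#' and returns, per query row, the smallest training response with
#' \eqn{\hat F \ge \tau}.
#'
#' @param model a `forest_model`.
#' @param Xnew feature matrix of query rows.
#' @param tau quantile level in (0, 1); may be a vector, in which case a
#'   matrix with one column per level is returned.
#' @return numeric vector (or matrix for vector `tau`) of conditional
#'   quantiles.
#' @export
predict_qrf <- function(model, Xnew, tau = 0.5) {
  if (any(tau <= 0 | tau >= 1)) stop("tau must lie strictly in (0, 1)")
  if (is.null(dim(Xnew))) Xnew <- matrix(Xnew, nrow = 1)
  Wt <- qrf_weights(model, Xnew)
  ord <- order(model$y)
  ys <- model$y[ord]
  Wo <- Wt[, ord, drop = FALSE]
  Fm <- t(apply(Wo, 1, cumsum))
  out <- sapply(tau, function(tt)
    ys[apply(Fm >= tt - 1e-9, 1, function(z) which(z)[1])])
  if (length(tau) == 1) {
    out <- as.numeric(out)
    names(out) <- rownames(Xnew)
    out
  } else {
    out <- matrix(out, nrow = nrow(Xnew),
                  dimnames = list(rownames(Xnew), paste0("q", tau)))
    out
  }
}
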