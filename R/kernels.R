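#' Center marker dosages for relationship-matrix construction
#'
#' Codes each marker column as \eqn{2 - 2p_j}, \eqn{1 - 2p_j}, \eqn{-2p_j}
#' for dosages 2, 1, 0 (i.e. subtracts twice the allele frequency), and
#' carries the VanRaden denominator \eqn{\sum_j 2 p_j (1 - p_j)}.
#' Supplying `freqs` (e.g. training-set frequencies when centering test
#' genotypes) avoids information leak from the test set.
#'
#' @param g a [genotype_matrix()] or plain dosage matrix without missing
#'   values (impute first).
#' @param freqs optional per-marker allele frequencies to center with; when
#'   `NULL` they are computed from `g`.
#' @return list of class `marker_coding` with `W` (centered matrix), `p`
#'   (frequencies) and `denom`.
#' @export
center_markers <- function(g, freqs = NULL) {
  X <- if (inherits(g, "genotype_matrix")) g$dosage else as.matrix(g)
  if (anyNA(X)) stop("missing dosages: run impute_missing() first")
  p <- if (is.null(freqs)) colMeans(X) / 2 else as.numeric(freqs)
  if (length(p) != ncol(X)) stop("freqs length must match marker count")
  denom <- sum(2 * p * (1 - p))
  if (denom <= 0)
    stop("all markers are monomorphic at the supplied frequencies")
  W <- sweep(X, 2, 2 * p)
  structure(list(W = W, p = p, denom = denom), class = "marker_coding")
}

#' VanRaden genomic relationship matrix
#'
#' \deqn{G = W W^\top / \sum_j 2 p_j (1 - p_j)} over the centered marker
#' matrix `W` (individuals in rows). When the frequencies are computed from
#' the same data, rows and columns of `G` sum to zero.
#'
#' @param mc a `marker_coding` from [center_markers()].
#' @return an n-by-n `kinship_matrix` (symmetric, sample ids as dimnames,
#'   source tag `"markers"`).
#' @export
grm_vanraden <- function(mc) {
  stopifnot(inherits(mc, "marker_coding"))
  if (nrow(mc$W) < 2) stop("need at least 2 individuals for a kinship matrix")
  K <- tcrossprod(mc$W) / mc$denom
  K <- (K + t(K)) / 2
  structure(list(K = K, ids = rownames(mc$W), source = "markers"),
            class = "kinship_matrix")
}

#' Kinship-like kernel from level-one prediction columns
#'
#' Standardizes each prediction column to mean 0 and (population) variance 1
#' and returns \eqn{K = P P^\top / q} over the `q` standardized columns.
#' This is the second kernel of the two-kernel stacking GBLUP. Constant
#' columns are dropped with a warning. Supplying `center`/`scale` (e.g.
#' training-column statistics) standardizes with those instead.
#'
#' @param P numeric matrix of prediction columns (individuals in rows).
#' @param center,scale optional per-column statistics to standardize with.
#' @return a `kinship_matrix` with source tag `"predictions"`.
#' @export
grm_from_predictions <- function(P, center = NULL, scale = NULL) {
  P <- as.matrix(P)
  if (is.null(center)) center <- colMeans(P)
  if (is.null(scale))
    scale <- sqrt(colMeans(sweep(P, 2, colMeans(P))^2))
  const <- scale < 1e-12
  if (all(const)) stop("all prediction columns are constant")
  if (any(const)) {
    warning("dropping ", sum(const), " constant prediction column(s)")
    P <- P[, !const, drop = FALSE]
    center <- center[!const]
    scale <- scale[!const]
  }
  Z <- sweep(sweep(P, 2, center), 2, scale, "/")
  K <- tcrossprod(Z) / ncol(Z)
  K <- (K + t(K)) / 2
  structure(list(K = K, ids = rownames(P), source = "predictions"),
            class = "kinship_matrix")
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("kinship_matrix (", x$source, "): ", nrow(x$K), " x ", ncol(x$K),
      ", mean diagonal ", sprintf("%.3f", mean(diag(x$K))), "\n", sep = "")
  invisible(x)
}

.as_K <- function(K) {
  if (inherits(K, "kinship_matrix")) K$K else as.matrix(K)
}

.check_psd <- function(K, tol = 1e-8) {
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -tol * max(abs(ev), 1))
    stop("kinship matrix is not positive semi-definite")
  invisible(ev)
}

#' Fit a single-kernel GBLUP model
#'
#' Fits \eqn{y^* = 1 b + u + e}, \eqn{u \sim N(0, K \sigma_g^2)},
#' \eqn{e \sim N(0, I \sigma_e^2)}. Variances are estimated by REML,
#' profiling the likelihood over the ratio \eqn{\sigma_g^2/\sigma_e^2} on
#' the spectral decomposition of `K`; pass `var_g`/`var_e` to fix them
#' instead.
#'
#' @param y named numeric vector of adjusted phenotypes, or an
#'   `adjusted_phenotypes` data.frame.
#' @param K a `kinship_matrix` (or plain matrix) covering at least the
#'   phenotyped ids.
#' @param var_g,var_e optional fixed variance components (skip REML).
#' @return object of class `gblup_model` with `b` (intercept), `var_g`,
#'   `var_e`, GEBVs `u` for the training individuals, and the
#'   eigendecomposition cache.
#' @export
fit_gblup <- function(y, K, var_g = NULL, var_e = NULL) {
  if (inherits(y, "adjusted_phenotypes"))
    y <- stats::setNames(y$y_star, y$id)
  Km <- .as_K(K)
  if (!is.null(names(y)) && !is.null(rownames(Km))) {
    if (!all(names(y) %in% rownames(Km)))
      stop("phenotyped id(s) missing from K")
    Km <- Km[names(y), names(y)]
  }
  n <- length(y)
  stopifnot(nrow(Km) == n)
  .check_psd(Km)
  eg <- eigen(Km, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  U <- eg$vectors
  yt <- crossprod(U, y)
  xt <- crossprod(U, rep(1, n))

  reml_neg2 <- function(log_ratio) {
    # ratio = var_g / var_e; profile out var_e and b
    r <- exp(log_ratio)
    v <- r * d + 1                      # V / var_e on the eigenbasis
    xvx <- sum(xt^2 / v)
    bhat <- sum(xt * yt / v) / xvx
    rt <- yt - xt * bhat
    ss <- sum(rt^2 / v)
    ve <- ss / (n - 1)
    (n - 1) * log(ve) + sum(log(v)) + log(xvx) + ss / ve
  }
  if (is.null(var_g) || is.null(var_e)) {
    opt <- stats::optimize(reml_neg2, c(-14, 14))
    ratio <- exp(opt$minimum)
    v <- ratio * d + 1
    xvx <- sum(xt^2 / v)
    bhat <- sum(xt * yt / v) / xvx
    rt <- yt - xt * bhat
    var_e <- sum(rt^2 / v) / (n - 1)
    var_g <- ratio * var_e
  } else {
    v <- if (var_e > 0) (var_g / var_e) * d + 1 else d * var_g + 1e-12
    if (var_e > 0) {
      xvx <- sum(xt^2 / v)
      bhat <- sum(xt * yt / v) / xvx
    } else bhat <- mean(y)
    rt <- yt - xt * bhat
  }
  # u = var_g K V^{-1} (y - 1 b) on the eigenbasis:
  # V = var_g D + var_e I
  vv <- var_g * d + var_e
  vv[vv < 1e-12] <- 1e-12
  u <- as.numeric(U %*% (var_g * d * (crossprod(U, y - bhat) / vv)))
  names(u) <- names(y)
  structure(list(b = bhat, var_g = var_g, var_e = var_e, u = u,
                 ids = names(y), eigen = eg, K = Km),
            class = "gblup_model")
}

#' @export
print.gblup_model <- function(x, ...) {
  cat("GBLUP fit: n =", length(x$u),
      sprintf("| var_g = %.4g, var_e = %.4g, b = %.4g\n",
              x$var_g, x$var_e, x$b))
  invisible(x)
}

#' Predict GEBVs for unphenotyped individuals from a GBLUP fit
#'
#' Extends training GEBVs to test individuals through the relationship
#' matrix: \eqn{\hat u_{test} = K_{test,train} K_{train,train}^{-1}
#' \hat u_{train}} (a small ridge is added to the inverse for stability).
#'
#' @param model a `gblup_model` from [fit_gblup()].
#' @param K_full `kinship_matrix` (or matrix) covering training and test ids.
#' @param test_ids character vector of ids to predict.
#' @param ridge diagonal stabilizer for the training-block inverse.
#' @return named numeric vector of test GEBVs.
#' @export
predict_gblup <- function(model, K_full, test_ids, ridge = 1e-8) {
  Km <- .as_K(K_full)
  train <- model$ids
  missing_ids <- setdiff(c(train, test_ids), rownames(Km))
  if (length(missing_ids))
    stop("id(s) missing from K_full: ", paste(utils::head(missing_ids, 3),
                                              collapse = ", "))
  Ktt <- Km[train, train]
  Kst <- Km[test_ids, train, drop = FALSE]
  sol <- solve(Ktt + diag(ridge, nrow(Ktt)), model$u)
  stats::setNames(as.numeric(Kst %*% sol), test_ids)
}

#' Fit a two-kernel GBLUP model
#'
#' Fits \eqn{y^* = 1b + u_1 + u_2 + e} with \eqn{u_k \sim N(0, K_k
#' \sigma_k^2)} by EM-REML on the mixed-model equations. Used as the
#' stacking meta-learner that combines a marker kernel with a kernel built
#' from base-learner predictions.
#'
#' @param y named numeric vector of adjusted phenotypes (or
#'   `adjusted_phenotypes`).
#' @param K1,K2 `kinship_matrix` objects (or matrices) over the phenotyped
#'   ids.
#' @param var1,var2,var_e optional fixed variances (skip REML for the fixed
#'   ones; all three must be given to skip entirely).
#' @param tol,maxit EM convergence controls.
#' @param ridge diagonal stabilizer added to each kernel before inversion.
#' @return object of class `gblup2k_model` with variances, intercept, and
#'   per-kernel GEBVs `u1`, `u2` (total prediction is their sum).
#' @export
fit_two_kernel_gblup <- function(y, K1, K2, var1 = NULL, var2 = NULL,
                                 var_e = NULL, tol = 1e-10, maxit = 1000,
                                 ridge = 1e-8) {
  if (inherits(y, "adjusted_phenotypes"))
    y <- stats::setNames(y$y_star, y$id)
  K1m <- .as_K(K1); K2m <- .as_K(K2)
  ids <- names(y)
  if (!is.null(ids) && !is.null(rownames(K1m))) {
    if (!all(ids %in% rownames(K1m)) || !all(ids %in% rownames(K2m)))
      stop("phenotyped id(s) missing from a kernel")
    K1m <- K1m[ids, ids]; K2m <- K2m[ids, ids]
  }
  n <- length(y)
  .check_psd(K1m); .check_psd(K2m)
  K1m <- K1m + diag(ridge, n)
  K2m <- K2m + diag(ridge, n)
  fixed <- c(!is.null(var1), !is.null(var2), !is.null(var_e))
  vy <- stats::var(y)
  if (!is.finite(vy) || vy <= 0) vy <- 1
  s1 <- if (fixed[1]) var1 else vy / 3
  s2 <- if (fixed[2]) var2 else vy / 3
  se <- if (fixed[3]) var_e else vy / 3
  s1 <- max(s1, 1e-12); s2 <- max(s2, 1e-12); se <- max(se, 1e-10)
  one <- matrix(1, n, 1)
  converged <- FALSE
  # EM-REML in the V / projection-matrix form: no kernel inverses needed,
  # so rank-deficient prediction kernels are handled exactly
  for (it in seq_len(maxit)) {
    V <- s1 * K1m + s2 * K2m + diag(se, n)
    Vi <- chol2inv(chol(V))
    ViX <- Vi %*% one
    XVX <- sum(one * ViX)
    P <- Vi - tcrossprod(ViX) / XVX
    Py <- P %*% y
    new1 <- if (fixed[1]) s1 else
      max(s1 + (s1^2 / n) * (sum(Py * (K1m %*% Py)) - sum(P * K1m)), 1e-12)
    new2 <- if (fixed[2]) s2 else
      max(s2 + (s2^2 / n) * (sum(Py * (K2m %*% Py)) - sum(P * K2m)), 1e-12)
    newe <- if (fixed[3]) se else
      max(se + (se^2 / n) * (sum(Py^2) - sum(diag(P))), 1e-10)
    delta <- max(abs(c(new1 - s1, new2 - s2, newe - se)) /
                   pmax(abs(c(s1, s2, se)), 1e-10))
    s1 <- new1; s2 <- new2; se <- newe
    if (delta < tol) { converged <- TRUE; break }
  }
  V <- s1 * K1m + s2 * K2m + diag(se, n)
  Vi <- chol2inv(chol(V))
  ViX <- Vi %*% one
  b <- sum(ViX * y) / sum(one * ViX)
  Vr <- Vi %*% (y - b)
  u1 <- as.numeric(s1 * K1m %*% Vr)
  u2 <- as.numeric(s2 * K2m %*% Vr)
  structure(list(b = b, var1 = s1, var2 = s2, var_e = se,
                 u1 = stats::setNames(u1, ids),
                 u2 = stats::setNames(u2, ids),
                 ids = ids, converged = converged, iterations = it),
            class = "gblup2k_model")
}

#' Predict total genetic values from a two-kernel GBLUP fit
#'
#' Each kernel's GEBVs are extended to test individuals through its own
#' relationship matrix (as in [predict_gblup()]) and the two components are
#' summed.
#'
#' @param model a `gblup2k_model`.
#' @param K1_full,K2_full kernels covering training and test ids.
#' @param test_ids ids to predict.
#' @param ridge diagonal stabilizer.
#' @return named numeric vector of summed test GEBVs.
#' @export
predict_two_kernel_gblup <- function(model, K1_full, K2_full, test_ids,
                                     ridge = 1e-8) {
  ext <- function(Kf, u) {
    Km <- .as_K(Kf)
    tr <- model$ids
    if (!all(test_ids %in% rownames(Km)))
      stop("test id(s) missing from a kernel")
    as.numeric(Km[test_ids, tr, drop = FALSE] %*%
                 solve(Km[tr, tr] + diag(ridge, length(tr)), u))
  }
  stats::setNames(ext(K1_full, model$u1) + ext(K2_full, model$u2), test_ids)
}
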