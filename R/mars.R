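#' Hinge basis function
#'
#' The reflected pair of piecewise-linear basis functions from which MARS
#' models are built: side `"+"` gives \eqn{(x - t)_+}, side `"-"` gives
#' \eqn{(t - x)_+}.
#'
#' @param x numeric value(s).
#' @param t knot.
#' @param side `"+"` or `"-"`.
#' @return numeric value(s).
#' @export
hinge <- function(x, t, side = c("+", "-")) {
  side <- match.arg(side)
  if (side == "+") pmax(x - t, 0) else pmax(t - x, 0)
}

# a term is a list of factors (j, t, s); the intercept is the empty list
.eval_term <- function(term, M) {
  v <- rep(1, nrow(M))
  for (f in term)
    v <- v * (if (f$s > 0) pmax(M[, f$j] - f$t, 0) else pmax(f$t - M[, f$j], 0))
  v
}

.eval_basis <- function(terms, M) {
  B <- vapply(terms, .eval_term, numeric(nrow(M)), M = M)
  matrix(B, nrow = nrow(M))
}

.term_label <- function(term) {
  if (!length(term)) return("(intercept)")
  paste(vapply(term, function(f)
    if (f$s > 0) sprintf("h(x%d-%g)", f$j, f$t)
    else sprintf("h(%g-x%d)", f$t, f$j), character(1)), collapse = "*")
}

# least squares with QR column pruning of numerically collinear terms
.ls_fit <- function(B, y, tol = 1e-10) {
  q <- qr(B, tol = tol)
  beta <- rep(0, ncol(B))
  cf <- qr.coef(q, y)
  cf[is.na(cf)] <- 0
  beta[seq_along(cf)] <- cf
  fit <- as.numeric(B %*% beta)
  list(beta = beta, rss = sum((y - fit)^2), rank = q$rank)
}

#' Forward basis construction for MARS
#'
#' Starting from the constant term, repeatedly adds the reflected hinge pair
#' (an existing term multiplied by \eqn{(x_j - t)_+} and \eqn{(t - x_j)_+})
#' that maximally reduces the training residual sum of squares, under the
#' interaction-degree limit and the rule that no term multiplies two hinges
#' on the same feature. Knots range over the observed values of each
#' feature. The pass stops at `max_terms` terms or when the best RSS
#' improvement falls below `thresh`.
#'
#' @param X numeric feature matrix.
#' @param y numeric response.
#' @param degree maximum number of hinge factors per term (1-3).
#' @param max_terms maximum number of basis terms including the intercept.
#' @param thresh minimum RSS improvement to keep adding (default 1e-10).
#' @return a list of class `mars_basis`: the term list and the forward RSS
#'   trace.
#' @export
mars_forward <- function(X, y, degree = 1, max_terms = 21, thresh = 1e-10) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(degree %in% 1:3, n == length(y))
  if (max_terms < 3) stop("max_terms must be >= 3")
  if (n < 2 * max_terms)
    warning("fewer than 2*max_terms rows; the forward pass may overfit")

  # candidate hinge columns for every (feature, observed-value knot)
  kn_j <- integer(0); kn_t <- numeric(0)
  for (j in seq_len(ncol(X))) {
    tt <- sort(unique(X[, j]))
    kn_j <- c(kn_j, rep.int(j, length(tt)))
    kn_t <- c(kn_t, tt)
  }
  if (length(kn_j) * n > 5e7)
    stop("too many knot candidates; reduce features or bin their values")
  Hp <- pmax(X[, kn_j, drop = FALSE] -
               matrix(kn_t, n, length(kn_t), byrow = TRUE), 0)
  Hm <- pmax(matrix(kn_t, n, length(kn_t), byrow = TRUE) -
               X[, kn_j, drop = FALSE], 0)

  terms <- list(list())          # intercept
  Q <- matrix(1 / sqrt(n), n, 1) # orthonormal basis of the span
  orth <- function(v) {
    v <- v - Q %*% crossprod(Q, v)
    v - Q %*% crossprod(Q, v)    # re-orthogonalize for stability
  }
  r <- as.numeric(orth(y))
  rss_trace <- sum(r^2)

  while (length(terms) + 2 <= max_terms) {
    best <- list(red = -Inf)
    for (m in seq_along(terms)) {
      parent <- terms[[m]]
      if (length(parent) >= degree) next
      pv <- .eval_term(parent, X)
      if (all(pv == 0)) next
      used <- vapply(parent, function(f) f$j, integer(1))
      ok <- !(kn_j %in% used)
      if (!any(ok)) next
      C1 <- Hp[, ok, drop = FALSE] * pv
      C2 <- Hm[, ok, drop = FALSE] * pv
      A1 <- crossprod(Q, C1); A2 <- crossprod(Q, C2)
      a <- pmax(colSums(C1^2) - colSums(A1^2), 0)
      d <- pmax(colSums(C2^2) - colSums(A2^2), 0)
      b <- colSums(C1 * C2) - colSums(A1 * A2)
      u <- as.numeric(crossprod(C1, r))
      v <- as.numeric(crossprod(C2, r))
      scale2 <- pmax(a, d, 1e-12)
      va <- a > 1e-10 * scale2
      vd <- d > 1e-10 * scale2
      det <- a * d - b^2
      both <- va & vd & det > 1e-10 * a * d
      red <- numeric(length(a))
      red[both] <- (d[both] * u[both]^2 - 2 * b[both] * u[both] * v[both] +
                      a[both] * v[both]^2) / det[both]
      one1 <- va & !both
      red[one1] <- u[one1]^2 / a[one1]
      one2 <- vd & !both & !va
      red[one2] <- v[one2]^2 / d[one2]
      k <- which.max(red)
      if (length(k) && red[k] > best$red) {
        kj <- which(ok)[k]
        best <- list(red = red[k], parent = m,
                     j = kn_j[kj], t = kn_t[kj])
      }
    }
    if (!is.finite(best$red) || best$red < thresh) break
    parent <- terms[[best$parent]]
    added <- FALSE
    for (s in c(1, -1)) {
      term <- c(parent, list(list(j = best$j, t = best$t, s = s)))
      col <- .eval_term(term, X)
      co <- orth(col)
      nrm <- sqrt(sum(co^2))
      if (nrm > 1e-8 * max(sqrt(sum(col^2)), 1e-12)) {
        terms <- c(terms, list(term))
        Q <- cbind(Q, co / nrm)
        added <- TRUE
      }
    }
    if (!added) break
    r <- as.numeric(orth(y))
    rss_trace <- c(rss_trace, sum(r^2))
  }
  structure(list(terms = terms, rss_trace = rss_trace, degree = degree,
                 max_terms = max_terms), class = "mars_basis")
}

#' Generalized cross-validation score for a MARS submodel
#'
#' \deqn{GCV = \frac{RSS/N}{(1 - C(M)/N)^2}, \quad
#' C(M) = M + d (M - 1)/2,} with `M` the number of basis terms including
#' the intercept and `d` the per-knot cost (default 3).
#'
#' @param rss residual sum of squares of the submodel.
#' @param n number of training observations.
#' @param n_terms number of terms, intercept included.
#' @param penalty per-knot cost `d` (default 3).
#' @return the GCV score; `Inf` when the effective parameter count reaches
#'   `n` (inadmissible submodel).
#' @export
gcv_mars <- function(rss, n, n_terms, penalty = 3) {
  cm <- n_terms + penalty * (n_terms - 1) / 2
  if (cm >= n) return(Inf)
  (rss / n) / (1 - cm / n)^2
}

#' Backward pruning of a MARS basis by GCV
#'
#' Walks the deletion path: at each step the non-intercept term whose
#' removal gives the lowest GCV is deleted; the submodel with the global
#' minimum GCV along the path (including the full model) is returned,
#' refitted by least squares.
#'
#' @param basis a `mars_basis` from [mars_forward()].
#' @param X,y the training data the basis was built on.
#' @param penalty GCV per-knot cost (default 3).
#' @return an object of class `mars_model`.
#' @export
mars_backward <- function(basis, X, y, penalty = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  terms <- basis$terms
  B <- .eval_basis(terms, X)
  current <- seq_along(terms)
  fit <- .ls_fit(B[, current, drop = FALSE], y)
  best <- list(idx = current, gcv = gcv_mars(fit$rss, n, length(current),
                                             penalty), beta = fit$beta)
  while (length(current) > 1) {
    cand_gcv <- rep(Inf, length(current))
    cand_fit <- vector("list", length(current))
    for (k in seq_along(current)[-1]) {   # never delete the intercept
      idx <- current[-k]
      f <- .ls_fit(B[, idx, drop = FALSE], y)
      cand_gcv[k] <- gcv_mars(f$rss, n, length(idx), penalty)
      cand_fit[[k]] <- f
    }
    k <- which.min(cand_gcv)
    current <- current[-k]
    f <- cand_fit[[k]]
    if (cand_gcv[k] <= best$gcv)
      best <- list(idx = current, gcv = cand_gcv[k], beta = f$beta)
  }
  terms_kept <- terms[best$idx]
  Bk <- B[, best$idx, drop = FALSE]
  f <- .ls_fit(Bk, y)
  structure(list(terms = terms_kept, beta = f$beta, rss = f$rss,
                 gcv = gcv_mars(f$rss, n, length(terms_kept), penalty),
                 degree = basis$degree, max_terms = basis$max_terms,
                 penalty = penalty,
                 labels = vapply(terms_kept, .term_label, character(1))),
            class = "mars_model")
}

#' Fit a multivariate adaptive regression splines model
#'
#' Runs the forward hinge-pair construction ([mars_forward()]) followed by
#' GCV backward pruning ([mars_backward()]). `degree` 1 gives an additive
#' model; 2 and 3 admit second- and third-order hinge interactions.
#'
#' @param X numeric feature matrix.
#' @param y numeric response.
#' @param degree interaction degree, 1-3.
#' @param max_terms maximum basis size of the forward pass (default 21).
#' @param penalty GCV per-knot cost (default 3).
#' @return an object of class `mars_model`.
#' @export
fit_mars <- function(X, y, degree = 1, max_terms = 21, penalty = 3) {
  basis <- mars_forward(X, y, degree = degree, max_terms = max_terms)
  mars_backward(basis, X, y, penalty = penalty)
}

#' @export
print.mars_model <- function(x, ...) {
  cat("MARS model (degree", x$degree, "):", length(x$terms), "terms, GCV =",
      signif(x$gcv, 5), "\n")
  for (i in seq_along(x$terms))
    cat(sprintf("  %+.4g * %s\n", x$beta[i], x$labels[i]))
  invisible(x)
}

#' Predict from a fitted MARS model
#' @param object a `mars_model`.
#' @param Xnew feature matrix.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.mars_model <- function(object, Xnew, ...) {
  Xnew <- as.matrix(Xnew)
  out <- as.numeric(.eval_basis(object$terms, Xnew) %*% object$beta)
  names(out) <- rownames(Xnew)
  out
}
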