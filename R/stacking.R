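#' Construct a base learner for the stacking framework
#'
#' A base learner couples a fitting engine with a prediction rule. Learners
#' sharing a `group` also share one fitted engine — the nine quantile-forest
#' learners differ only in the quantile read off one fitted forest, so the
#' forest is trained once per group.
#'
#' @param name column name the learner contributes to the level-one data.
#' @param fit function `(X, y) -> engine` over a complete dosage matrix
#'   (rows named by individual) and a named response.
#' @param predict function `(engine, Xnew) -> numeric` of test predictions.
#' @param group engine-sharing key (default: the learner's own name).
#' @return a list of class `base_learner`.
#' @export
base_learner <- function(name, fit, predict, group = name) {
  structure(list(name = name, fit = fit, predict = predict, group = group),
            class = "base_learner")
}

.gblup_learner_fit <- function(X, y) {
  mc <- center_markers(X)
  K <- grm_vanraden(mc)
  gb <- fit_gblup(stats::setNames(y, rownames(X)), K)
  list(gb = gb, W = mc$W, p = mc$p, denom = mc$denom)
}

.gblup_learner_predict <- function(engine, Xnew, ridge = 1e-8) {
  Wn <- sweep(as.matrix(Xnew), 2, 2 * engine$p)
  Kc <- tcrossprod(Wn, engine$W) / engine$denom
  Ktt <- tcrossprod(engine$W) / engine$denom
  as.numeric(Kc %*% solve(Ktt + diag(ridge, nrow(Ktt)), engine$gb$u)) +
    engine$gb$b
}

#' The fourteen default base learners
#'
#' GBLUP, MARS of degrees 1-3, quantile regression forests at the nine
#' quantiles 0.1-0.9 (one shared forest), and a random forest.
#'
#' @param n_trees forest size for RF and QRF (default 500).
#' @param min_node forest leaf-size control (default 5).
#' @param mars_max_terms forward-pass cap for the MARS learners.
#' @param taus quantile levels for the QRF learners.
#' @return list of [base_learner()] objects.
#' @export
base_learner_set <- function(n_trees = 500, min_node = 5,
                             mars_max_terms = 21,
                             taus = seq(0.1, 0.9, by = 0.1)) {
  out <- list(base_learner(
    "GBLUP", .gblup_learner_fit, .gblup_learner_predict))
  for (dg in 1:3) {
    local({
      d <- dg
      out[[length(out) + 1]] <<- base_learner(
        paste0("MARS", d),
        function(X, y) fit_mars(X, y, degree = d,
                                max_terms = mars_max_terms),
        function(engine, Xnew) predict(engine, Xnew))
    })
  }
  for (tt in taus) {
    local({
      tau <- tt
      out[[length(out) + 1]] <<- base_learner(
        sprintf("QRF%.1f", tau),
        function(X, y) fit_rf(X, y, n_trees = n_trees, min_node = min_node),
        function(engine, Xnew) predict_qrf(engine, Xnew, tau = tau),
        group = "QRF")
    })
  }
  out[[length(out) + 1]] <- base_learner(
    "RF",
    function(X, y) fit_rf(X, y, n_trees = n_trees, min_node = min_node),
    function(engine, Xnew) predict(engine, Xnew))
  out
}

#' Level-one metadata from out-of-fold base-learner predictions
#'
#' Splits the training set into `k_inner` folds; each base learner is fitted
#' on the complement of a fold and predicts it, so every training individual
#' receives an out-of-fold prediction from every learner. These columns form
#' the level-one data, the per-learner inner predictive ability (Pearson
#' correlation of the out-of-fold column with the response) drives the
#' best-learner rule, and the learners are then refit on the full training
#' set for test-time use. Set `naive = TRUE` to use in-sample predictions
#' instead (the literal single-fit reading, which leaks training
#' information into the meta-learner).
#'
#' @param learners list of [base_learner()] objects.
#' @param X complete training dosage matrix, rows named by individual.
#' @param y named numeric response (adjusted phenotypes), aligned with `X`.
#' @param k_inner number of inner folds (default 5).
#' @param seed optional RNG seed.
#' @param naive use in-sample instead of out-of-fold predictions.
#' @return an object of class `level_one_data` with the prediction matrix
#'   `Z`, `inner_pa`, the refit `engines`, and the variant tag `"GEBV-BL"`.
#' @export
generate_level_one <- function(learners, X, y, k_inner = 5, seed = NULL,
                               naive = FALSE) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(n == length(y))
  if (is.null(names(y))) names(y) <- rownames(X)
  if (!is.null(seed)) set.seed(seed)
  groups <- split(learners, vapply(learners, `[[`, character(1), "group"))
  lnames <- vapply(learners, `[[`, character(1), "name")

  Z <- matrix(NA_real_, n, length(learners),
              dimnames = list(rownames(X), lnames))
  failed <- character(0)
  if (naive) {
    for (grp in groups) {
      eng <- tryCatch(grp[[1]]$fit(X, y), error = function(e) e)
      for (lrn in grp) {
        if (inherits(eng, "error")) { failed <- c(failed, lrn$name); next }
        Z[, lrn$name] <- tryCatch(lrn$predict(eng, X), error = function(e) {
          failed <<- c(failed, lrn$name); rep(NA_real_, n) })
      }
    }
  } else {
    fold <- sample(rep(seq_len(k_inner), length.out = n))
    for (f in seq_len(k_inner)) {
      tr <- fold != f
      for (grp in groups) {
        eng <- tryCatch(grp[[1]]$fit(X[tr, , drop = FALSE], y[tr]),
                        error = function(e) e)
        for (lrn in grp) {
          if (inherits(eng, "error")) { failed <- c(failed, lrn$name); next }
          Z[!tr, lrn$name] <- tryCatch(
            lrn$predict(eng, X[!tr, , drop = FALSE]),
            error = function(e) { failed <<- c(failed, lrn$name)
              rep(NA_real_, sum(!tr)) })
        }
      }
    }
  }
  # refit every surviving engine group on the full training set for
  # test-time use; a refit failure drops the group's learners as well
  keep_groups <- unique(vapply(learners[!lnames %in% failed], `[[`,
                               character(1), "group"))
  engines <- list()
  for (gname in keep_groups) {
    eng <- tryCatch(groups[[gname]][[1]]$fit(X, y), error = function(e) e)
    if (inherits(eng, "error"))
      failed <- c(failed, vapply(groups[[gname]], `[[`, character(1), "name"))
    else engines[[gname]] <- eng
  }
  failed <- unique(failed)
  if (length(failed)) {
    warning("dropping base learner column(s) that failed: ",
            paste(failed, collapse = ", "))
    Z <- Z[, setdiff(colnames(Z), failed), drop = FALSE]
    learners <- learners[!lnames %in% failed]
  }
  inner_pa <- apply(Z, 2, function(col)
    suppressWarnings(stats::cor(col, y)))
  structure(list(Z = Z, inner_pa = inner_pa, learners = learners,
                 engines = engines, y = y, variant = "GEBV-BL",
                 snp_W = NULL, snp_p = NULL, snp_denom = NULL,
                 best = NULL, k_inner = k_inner, naive = naive),
            class = "level_one_data")
}

#' @export
print.level_one_data <- function(x, ...) {
  cat("level-one data (", x$variant, "): ", nrow(x$Z), " individuals x ",
      ncol(x$Z), " learner columns",
      if (!is.null(x$snp_W)) paste0(" + ", ncol(x$snp_W), " SNP columns"),
      "\n", sep = "")
  invisible(x)
}

#' Select base learners exceeding the average predictive ability
#'
#' Returns the learners whose inner predictive ability is strictly greater
#' than the mean over all learners. When none strictly exceeds the mean
#' (all abilities equal), all learners are returned with a warning.
#'
#' @param pa named numeric vector of per-learner predictive abilities.
#' @return character vector of selected learner names.
#' @export
select_best <- function(pa) {
  if (all(!is.finite(pa))) stop("no learner has a finite predictive ability")
  if (any(!is.finite(pa))) {
    warning("ignoring learner(s) with undefined predictive ability")
    pa <- pa[is.finite(pa)]
  }
  sel <- names(pa)[pa > mean(pa)]
  if (!length(sel)) {
    warning("no learner exceeds the mean predictive ability; keeping all")
    sel <- names(pa)
  }
  sel
}

.VARIANTS <- c("GEBV-BL", "GEBV-BL+SNP", "GEBV-BL-Best", "GEBV-BL-Best+SNP")

#' Assemble a level-one metadata variant
#'
#' Applies the best-learner column subset (`-Best` variants) and attaches
#' the centered SNP block (`+SNP` variants) to level-one data.
#'
#' @param L a `level_one_data` object.
#' @param variant one of `"GEBV-BL"`, `"GEBV-BL+SNP"`, `"GEBV-BL-Best"`,
#'   `"GEBV-BL-Best+SNP"`.
#' @param snp list with the training-frequency-centered SNP block: `W`
#'   (matrix aligned with `L$Z` rows), `p`, `denom` (as produced by
#'   [center_markers()]). Required for the `+SNP` variants.
#' @return a new `level_one_data` tagged with the variant.
#' @export
build_metadata <- function(L, variant = .VARIANTS, snp = NULL) {
  variant <- match.arg(variant)
  out <- L
  if (grepl("Best", variant)) {
    if (is.null(L$inner_pa) || all(!is.finite(L$inner_pa)))
      stop("Best variant requested but inner predictive abilities are absent")
    keep <- select_best(L$inner_pa)
    out$Z <- L$Z[, keep, drop = FALSE]
    out$best <- keep
  }
  if (grepl("\\+SNP", variant, fixed = FALSE)) {
    if (is.null(snp)) stop("variant ", variant, " requires the SNP block")
    stopifnot(nrow(snp$W) == nrow(L$Z))
    out$snp_W <- snp$W
    out$snp_p <- snp$p
    out$snp_denom <- snp$denom
  } else {
    out$snp_W <- out$snp_p <- out$snp_denom <- NULL
  }
  out$variant <- variant
  out
}

# Lawson-Hanson non-negative least squares
.nnls <- function(A, b, tol = 1e-10, maxit = 10 * ncol(A) + 50) {
  p <- ncol(A)
  x <- numeric(p)
  P <- logical(p)
  w <- as.numeric(crossprod(A, b))
  for (it in seq_len(maxit)) {
    if (all(P) || max(w[!P]) <= tol) break
    P[which(!P)[which.max(w[!P])]] <- TRUE
    repeat {
      s <- numeric(p)
      sp <- qr.coef(qr(A[, P, drop = FALSE]), b)
      sp[is.na(sp)] <- 0
      s[P] <- sp
      if (all(s[P] > tol)) { x <- s; break }
      ip <- which(P)[s[P] <= tol]
      alpha <- min(x[ip] / (x[ip] - s[ip] + 1e-300))
      x <- x + alpha * (s - x)
      P <- P & x > tol
      x[!P] <- 0
      if (!any(P)) break
    }
    w <- as.numeric(crossprod(A, b - A %*% x))
  }
  x
}

# ridge regression with unpenalized intercept on standardized columns
.ridge_fit <- function(M, y, lambda) {
  mu <- colMeans(M)
  sdv <- sqrt(colMeans(sweep(M, 2, mu)^2))
  sdv[sdv < 1e-12] <- 1
  Z <- sweep(sweep(M, 2, mu), 2, sdv, "/")
  ym <- mean(y)
  if (!is.finite(lambda)) {
    beta <- numeric(ncol(M))
  } else {
    sv <- svd(Z)
    keep <- sv$d > 1e-12 * max(sv$d, 1)
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((sv$d[keep] / (sv$d[keep]^2 + lambda)) *
         crossprod(sv$u[, keep, drop = FALSE], y - ym))
    beta <- as.numeric(beta)
  }
  list(beta = beta, mu = mu, sd = sdv, intercept = ym, lambda = lambda)
}

.ridge_predict <- function(fit, Mnew) {
  Z <- sweep(sweep(Mnew, 2, fit$mu), 2, fit$sd, "/")
  as.numeric(fit$intercept + Z %*% fit$beta)
}

.ridge_lambda_grid <- function() exp(seq(log(1e-4), log(1e4), length.out = 50))

.meta_design <- function(L) {
  if (is.null(L$snp_W)) L$Z else cbind(L$Z, L$snp_W)
}

#' Fit a stacking meta-learner
#'
#' The six meta-learners combine the level-one metadata into a single
#' prediction:
#' * `SSM` — simple (unweighted) mean of the learner columns;
#' * `SWR` — weighted regression: least squares with non-negative weights
#'   over the learner columns, normalized to sum to one;
#' * `SR` — ordinary least squares with intercept on the metadata (learner
#'   columns plus SNP block when present), falling back to a minimum-norm
#'   pseudo-inverse solution when collinear;
#' * `SRR` — ridge regression on standardized metadata columns, penalty
#'   chosen by inner 5-fold cross-validation over a 50-point log grid on
#'   `[1e-4, 1e4]` (overridable via `lambda`);
#' * `SRF` — random forest on the metadata columns;
#' * `S2KGBLUP` — two-kernel GBLUP with a VanRaden marker kernel and a
#'   kernel of standardized learner predictions; only valid for `+SNP`
#'   variants.
#'
#' @param kind one of `"SSM"`, `"SWR"`, `"SR"`, `"SRR"`, `"SRF"`,
#'   `"S2KGBLUP"`.
#' @param L a `level_one_data` (after [build_metadata()]).
#' @param y named training response aligned with `L$Z` rows; defaults to the
#'   response stored in `L`.
#' @param lambda optional fixed ridge penalty for `SRR` (`Inf` shrinks to
#'   the training mean).
#' @param n_trees forest size for `SRF`.
#' @return object of class `meta_model`.
#' @export
fit_meta <- function(kind = c("SSM", "SWR", "SR", "SRR", "SRF", "S2KGBLUP"),
                     L, y = NULL, lambda = NULL, n_trees = 500) {
  kind <- match.arg(kind)
  if (is.null(y)) y <- L$y
  Z <- L$Z
  stopifnot(nrow(Z) == length(y))
  fit <- switch(kind,
    SSM = list(),
    SWR = {
      w <- .nnls(Z, y)
      if (sum(w) < 1e-12) {
        warning("all SWR weights zero; falling back to equal weights")
        w <- rep(1, ncol(Z))
      }
      list(w = w / sum(w))
    },
    SR = {
      M <- cbind(1, .meta_design(L))
      q <- qr(M)
      if (q$rank < ncol(M)) {
        warning("collinear metadata columns; SR uses the pseudo-inverse ",
                "(minimum-norm) solution")
        beta <- as.numeric(MASS::ginv(M) %*% y)
      } else {
        beta <- qr.coef(q, y)
      }
      list(beta = beta)
    },
    SRR = {
      M <- .meta_design(L)
      if (is.null(lambda)) {
        grid <- .ridge_lambda_grid()
        fold <- sample(rep(seq_len(5), length.out = nrow(M)))
        errs <- sapply(grid, function(lm) {
          se <- 0
          for (f in seq_len(5)) {
            tr <- fold != f
            ft <- .ridge_fit(M[tr, , drop = FALSE], y[tr], lm)
            se <- se + sum((y[!tr] -
                              .ridge_predict(ft, M[!tr, , drop = FALSE]))^2)
          }
          se
        })
        lambda <- grid[which.min(errs)]
      }
      .ridge_fit(M, y, lambda)
    },
    SRF = list(forest = fit_rf(.meta_design(L), y, n_trees = n_trees)),
    S2KGBLUP = {
      if (is.null(L$snp_W))
        stop("S2KGBLUP requires a +SNP metadata variant")
      K1 <- structure(list(K = tcrossprod(L$snp_W) / L$snp_denom,
                           ids = rownames(Z), source = "markers"),
                      class = "kinship_matrix")
      zc <- colMeans(Z)
      zs <- sqrt(colMeans(sweep(Z, 2, zc)^2))
      K2 <- grm_from_predictions(Z, center = zc, scale = zs)
      m2k <- fit_two_kernel_gblup(stats::setNames(y, rownames(Z)), K1, K2)
      list(model = m2k, z_center = zc, z_scale = zs)
    })
  structure(list(kind = kind, fit = fit, variant = L$variant,
                 learner_cols = colnames(Z), has_snp = !is.null(L$snp_W)),
            class = "meta_model")
}

#' @export
print.meta_model <- function(x, ...) {
  cat("meta-learner", x$kind, "on variant", x$variant, "with",
      length(x$learner_cols), "learner column(s)\n")
  invisible(x)
}

#' Final stacked prediction for test individuals
#'
#' Applies the refit base learners to the test genotypes, assembles the
#' metadata variant the meta-learner was trained on (same learner subset,
#' SNP block centered with training frequencies), and applies the
#' meta-learner. For `S2KGBLUP` both kernels are extended over the combined
#' training and test individuals.
#'
#' @param meta a `meta_model` from [fit_meta()].
#' @param L the `level_one_data` the meta-learner was fitted on (carries
#'   the refit engines and SNP centering statistics).
#' @param X_test complete test dosage matrix (same markers as training).
#' @return named numeric vector of test predictions.
#' @export
predict_stack <- function(meta, L, X_test) {
  X_test <- as.matrix(X_test)
  if (meta$variant != L$variant)
    stop("metadata variant mismatch: meta-learner was trained on ",
         meta$variant, ", level-one data is ", L$variant)
  Zt <- base_predictions(L, X_test)[, meta$learner_cols, drop = FALSE]
  snp_t <- if (meta$has_snp) sweep(X_test, 2, 2 * L$snp_p) else NULL
  out <- switch(meta$kind,
    SSM = rowMeans(Zt),
    SWR = as.numeric(Zt %*% meta$fit$w),
    SR = {
      M <- cbind(1, if (is.null(snp_t)) Zt else cbind(Zt, snp_t))
      as.numeric(M %*% meta$fit$beta)
    },
    SRR = {
      M <- if (is.null(snp_t)) Zt else cbind(Zt, snp_t)
      .ridge_predict(meta$fit, M)
    },
    SRF = {
      M <- if (is.null(snp_t)) Zt else cbind(Zt, snp_t)
      as.numeric(predict(meta$fit$forest, M))
    },
    S2KGBLUP = {
      m <- meta$fit$model
      tr <- m$ids
      ridge <- 1e-8
      K1tt <- tcrossprod(L$snp_W) / L$snp_denom
      K1ct <- tcrossprod(snp_t, L$snp_W) / L$snp_denom
      Ztr <- sweep(sweep(L$Z[, meta$learner_cols, drop = FALSE], 2,
                         meta$fit$z_center), 2, meta$fit$z_scale, "/")
      Zte <- sweep(sweep(Zt, 2, meta$fit$z_center), 2,
                   meta$fit$z_scale, "/")
      q <- ncol(Ztr)
      K2tt <- tcrossprod(Ztr) / q
      K2ct <- tcrossprod(Zte, Ztr) / q
      u1 <- as.numeric(K1ct %*% solve(K1tt + diag(ridge, nrow(K1tt)), m$u1))
      u2 <- as.numeric(K2ct %*% solve(K2tt + diag(ridge, nrow(K2tt)), m$u2))
      m$b + u1 + u2
    })
  stats::setNames(as.numeric(out), rownames(X_test))
}

#' Base-learner predictions for new individuals
#'
#' Applies every refit base learner stored in a `level_one_data` object to
#' a new dosage matrix.
#'
#' @param L a `level_one_data` from [generate_level_one()].
#' @param X_new complete dosage matrix.
#' @return matrix with one named column per base learner.
#' @export
base_predictions <- function(L, X_new) {
  X_new <- as.matrix(X_new)
  out <- sapply(L$learners, function(lrn)
    lrn$predict(L$engines[[lrn$group]], X_new))
  matrix(out, nrow = nrow(X_new),
         dimnames = list(rownames(X_new),
                         vapply(L$learners, `[[`, character(1), "name")))
}
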