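#' EM-REML fit of the multi-year progeny-trial mixed model
#'
#' Fits, by expectation-maximisation REML, the Gaussian mixed model
#' \deqn{y = Xu + Zg + Wp + Vr + Tb + Ri + e}
#' with fixed year means `u` and independent random effects: progeny genetic
#' effects `g`, individual permanent environment `p`, population `r`, plot
#' `b`, year-by-progeny interaction `i`, and residual `e`, each with its own
#' variance component and identity covariance.
#'
#' Random terms whose classification has fewer than two levels are dropped
#' with a warning, as is the permanent-environment term when no individual
#' has repeated records and the year-by-progeny term when only one year is
#' present (both would otherwise duplicate another term's design).
#'
#' @param records a [pheno_records()] data.frame.
#' @param trait trait to fit; defaults to the single trait present.
#' @param tol convergence tolerance on the maximum relative change of any
#'   variance component (default 1e-8).
#' @param maxit maximum EM iterations (default 500).
#' @param floor lower bound applied to every component (default 1e-10).
#' @return an object of class `variance_components`: the component estimates
#'   (`sigma_g2`, `sigma_p2`, `sigma_r2`, `sigma_b2`, `sigma_i2`,
#'   `sigma_e2`; dropped terms are `NA`), fixed-effect year solutions,
#'   random-effect BLUPs, the REML log-likelihood trace, iteration count and
#'   convergence flag.
#' @export
fit_vc_reml <- function(records, trait = NULL, tol = 1e-8, maxit = 500,
                        floor = 1e-10) {
  records <- pheno_records(as.data.frame(records))
  traits <- unique(records$trait)
  if (is.null(trait)) {
    if (length(traits) > 1)
      stop("multiple traits present; pass trait explicitly")
    trait <- traits
  }
  rec <- records[records$trait == trait, , drop = FALSE]
  if (!nrow(rec)) stop("no records for trait ", trait)
  y <- rec$value
  n <- length(y)

  year <- factor(rec$year)
  X <- if (nlevels(year) > 1) stats::model.matrix(~ 0 + year)
       else matrix(1, n, 1)
  colnames(X) <- levels(year)
  if (qr(X)$rank < ncol(X)) stop("singular fixed-effect (year) design")
  p_fix <- ncol(X)

  reps_per_id <- max(table(rec$id))
  factors <- list(
    g = factor(rec$progeny),
    p = factor(rec$id),
    r = factor(rec$population),
    b = factor(rec$plot),
    i = interaction(rec$year, rec$progeny, drop = TRUE))
  drop_reason <- character(0)
  keep <- vapply(names(factors), function(k) {
    f <- factors[[k]]
    if (nlevels(f) < 2) {
      drop_reason[[k]] <<- "single level"
      return(FALSE)
    }
    if (k == "p" && reps_per_id < 2) {
      drop_reason[[k]] <<- "no repeated records per individual"
      return(FALSE)
    }
    if (k == "i" && nlevels(year) < 2) {
      drop_reason[[k]] <<- "single year"
      return(FALSE)
    }
    TRUE
  }, logical(1))
  if (length(drop_reason))
    warning("dropped random term(s): ",
            paste(names(drop_reason), "(", drop_reason, ")", collapse = ", "))
  factors <- factors[keep]
  K <- length(factors)
  if (K == 0) stop("no random terms left to fit")

  Zs <- lapply(factors, function(f) {
    Z <- stats::model.matrix(~ 0 + f)
    colnames(Z) <- levels(f)
    Z
  })
  qk <- vapply(Zs, ncol, integer(1))
  Wm <- cbind(X, do.call(cbind, Zs))
  C0 <- crossprod(Wm)
  rhs <- crossprod(Wm, y)
  yy <- sum(y^2)
  blk <- split(p_fix + seq_len(sum(qk)),
               rep(seq_len(K), qk))

  vy <- stats::var(y)
  if (!is.finite(vy) || vy < floor) vy <- 1
  sig <- c(rep(vy / (2 * K), K), vy / 2)  # K random + residual
  loglik <- numeric(0)
  converged <- FALSE
  it <- 0
  while (it < maxit) {
    it <- it + 1
    se2 <- sig[K + 1]
    C <- C0 / se2
    for (k in seq_len(K)) {
      ix <- blk[[k]]
      diag(C)[ix] <- diag(C)[ix] + 1 / sig[k]
    }
    ch <- tryCatch(chol(C), error = function(e) NULL)
    if (is.null(ch)) {
      diag(C) <- diag(C) + 1e-8
      ch <- chol(C)
    }
    sol <- backsolve(ch, forwardsolve(t(ch), rhs / se2))
    Ci <- chol2inv(ch)
    yPy <- (yy - sum(sol * rhs)) / se2
    ll <- -0.5 * (n * log(se2) + sum(qk * log(sig[seq_len(K)])) +
                    2 * sum(log(diag(ch))) + yPy)
    loglik <- c(loglik, ll)
    new <- sig
    for (k in seq_len(K)) {
      ix <- blk[[k]]
      uk <- sol[ix]
      new[k] <- max((sum(uk^2) + sum(diag(Ci)[ix])) / qk[k], floor)
    }
    new[K + 1] <- max((yy - sum(sol * rhs)) / (n - p_fix), floor)
    delta <- max(abs(new - sig) / pmax(abs(sig), floor))
    sig <- new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("EM-REML did not converge in ", maxit, " iterations")

  beta <- stats::setNames(sol[seq_len(p_fix)], colnames(X))
  blups <- lapply(seq_len(K), function(k)
    stats::setNames(sol[blk[[k]]], colnames(Zs[[k]])))
  names(blups) <- names(factors)

  comp <- stats::setNames(rep(NA_real_, 6),
                          c("sigma_g2", "sigma_p2", "sigma_r2", "sigma_b2",
                            "sigma_i2", "sigma_e2"))
  comp[paste0("sigma_", names(factors), "2")] <- sig[seq_len(K)]
  comp["sigma_e2"] <- sig[K + 1]

  structure(list(components = comp, beta = beta, blups = blups,
                 dropped = names(drop_reason), trait = trait,
                 n_records = n, iterations = it, converged = converged,
                 loglik = loglik), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("EM-REML variance components (trait:", x$trait, ")\n")
  comp <- x$components[!is.na(x$components)]
  for (k in names(comp)) cat(sprintf("  %-9s %.6g\n", k, comp[k]))
  cat("  iterations:", x$iterations,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  if (length(x$dropped)) cat("  dropped terms:",
                             paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Individual heritability from fitted variance components
#'
#' Computes \eqn{h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_p^2 + \sigma_r^2 +
#' \sigma_i^2 + \sigma_e^2)}. The plot component is excluded from the
#' denominator by default, mirroring the standard progeny-trial formula;
#' set `include_plot = TRUE` to add it.
#'
#' @param vc a `variance_components` fit (or a named numeric vector with the
#'   same component names).
#' @param include_plot include `sigma_b2` in the denominator.
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(vc, include_plot = FALSE) {
  comp <- if (inherits(vc, "variance_components")) vc$components else vc
  comp[is.na(comp)] <- 0
  den <- sum(comp[c("sigma_g2", "sigma_p2", "sigma_r2", "sigma_i2",
                    "sigma_e2")])
  if (include_plot) den <- den + comp["sigma_b2"]
  if (den <= 0) stop("all variance components are zero")
  as.numeric(comp["sigma_g2"] / den)
}

#' Adjusted phenotypes for genomic prediction
#'
#' Produces one value per individual by removing the estimated year, plot
#' and year-by-progeny effects from every record and averaging over an
#' individual's records:
#' \deqn{y^*_i = \mathrm{mean}_j (y_{ij} - \hat u_{year} - \hat b_{plot} -
#' \hat i_{year \times progeny}).}
#' Progeny, permanent-environment and population effects are deliberately
#' left in \eqn{y^*} so that the genetic signal survives for the learners.
#'
#' @param records a [pheno_records()] data.frame.
#' @param vc a fitted `variance_components` from [fit_vc_reml()].
#' @return data.frame of class `adjusted_phenotypes` with columns `id`,
#'   `trait`, `y_star`; the removed effects are recorded in attribute
#'   `"provenance"`.
#' @export
adjust_phenotypes <- function(records, vc) {
  records <- pheno_records(as.data.frame(records))
  rec <- records[records$trait == vc$trait, , drop = FALSE]
  if (!nrow(rec)) stop("no records for trait ", vc$trait)
  adj <- rec$value - vc$beta[rec$year]
  if ("b" %in% names(vc$blups))
    adj <- adj - vc$blups$b[rec$plot]
  if ("i" %in% names(vc$blups)) {
    key <- as.character(interaction(rec$year, rec$progeny, drop = TRUE))
    adj <- adj - vc$blups$i[key]
  }
  ystar <- tapply(adj, rec$id, mean)
  out <- data.frame(id = names(ystar), trait = vc$trait,
                    y_star = as.numeric(ystar), stringsAsFactors = FALSE,
                    row.names = NULL)
  stopifnot(all(is.finite(out$y_star)))
  class(out) <- c("adjusted_phenotypes", "data.frame")
  attr(out, "provenance") <- c("year", "plot", "year_progeny")
  out
}
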