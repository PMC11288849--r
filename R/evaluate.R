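#' Repeated holdout split plan
#'
#' Draws `n_reps` independent uniform random partitions of `n` individuals
#' into a training set of `floor(frac * n)` and a test set of the rest.
#'
#' @param n number of individuals.
#' @param frac training fraction (default 0.7).
#' @param n_reps number of replicates (default 10).
#' @param seed RNG seed.
#' @return object of class `split_plan`: per-replicate `train`/`test` index
#'   vectors plus the sizes and seed.
#' @export
make_splits <- function(n, frac = 0.7, n_reps = 10, seed = NULL) {
  if (n < 10) stop("need at least 10 individuals")
  if (frac <= 0 || frac >= 1) stop("frac must lie strictly in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_train <- floor(frac * n)
  reps <- lapply(seq_len(n_reps), function(r) {
    tr <- sort(sample.int(n, n_train))
    list(train = tr, test = setdiff(seq_len(n), tr))
  })
  structure(list(n = n, frac = frac, n_reps = n_reps, n_train = n_train,
                 n_test = n - n_train, reps = reps, seed = seed),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat("split plan:", x$n_reps, "replicates of", x$n_train, "train /",
      x$n_test, "test (n =", x$n, ")\n")
  invisible(x)
}

#' Predictive ability (Pearson correlation)
#'
#' @param pred predicted GEBVs.
#' @param obs observed adjusted phenotypes.
#' @return Pearson correlation, or `NA` (with a warning) if either vector
#'   is constant.
#' @export
predictive_ability <- function(pred, obs) {
  stopifnot(length(pred) == length(obs), length(pred) >= 3)
  if (anyNA(pred) || anyNA(obs)) {
    warning("missing value(s): predictive ability undefined")
    return(NA_real_)
  }
  if (stats::sd(pred) < 1e-12 || stats::sd(obs) < 1e-12) {
    warning("constant vector: predictive ability undefined")
    return(NA_real_)
  }
  stats::cor(pred, obs)
}

#' Mean squared error
#' @param pred predicted values.
#' @param obs observed values.
#' @return mean of squared differences.
#' @export
mse <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  mean((pred - obs)^2)
}

#' Top-decile agreement between two rankings
#'
#' Fraction of individuals shared between the top `ceil(frac * n)` of two
#' prediction vectors. Ties at the selection boundary are broken by
#' original index order (stable).
#'
#' @param a,b prediction vectors of equal length.
#' @param frac selected fraction (default 0.1).
#' @return agreement in `[0, 1]`.
#' @export
top_decile_agreement <- function(a, b, frac = 0.1) {
  stopifnot(length(a) == length(b))
  n <- length(a)
  if (frac * n < 1) stop("frac * n must be at least 1")
  k <- ceiling(frac * n)
  top <- function(v) order(-v, seq_len(n), method = "radix")[seq_len(k)]
  length(intersect(top(a), top(b))) / k
}

.meta_kinds_for <- function(variant) {
  if (grepl("\\+SNP", variant))
    c("SSM", "SWR", "SR", "SRR", "SRF", "S2KGBLUP")
  else c("SSM", "SWR", "SR", "SRR", "SRF")
}

.method_label <- function(kind, variant) {
  suffix <- switch(variant,
                   "GEBV-BL" = "",
                   "GEBV-BL+SNP" = "+SNP",
                   "GEBV-BL-Best" = "Best",
                   "GEBV-BL-Best+SNP" = "Best+SNP")
  paste0(kind, suffix)
}

#' Run the full stacking evaluation experiment
#'
#' For each holdout replicate: fits all base learners on the training set
#' with inner out-of-fold level-one generation, builds the requested
#' metadata variants, fits the requested meta-learners, predicts the test
#' set with every base and stacked method, and scores predictive ability
#' and MSE against the adjusted phenotypes. Pairwise Spearman and
#' top-decile agreement matrices are computed on the test predictions
#' pooled over replicates.
#'
#' @param geno a complete [genotype_matrix()] (impute first) or dosage
#'   matrix.
#' @param ystar adjusted phenotypes: an `adjusted_phenotypes` data.frame or
#'   a named numeric vector covering the genotyped individuals.
#' @param plan optional [make_splits()] plan (built from `seed` otherwise).
#' @param variants metadata variants to evaluate (default: all four).
#' @param meta_kinds meta-learners to evaluate (default: all valid per
#'   variant).
#' @param learners base learners (default [base_learner_set()]).
#' @param k_inner inner folds for level-one generation.
#' @param n_reps,frac holdout protocol controls (used when `plan` is NULL).
#' @param seed master seed for the whole experiment.
#' @param trait trait label for the report.
#' @return object of class `eval_report`: `summary` (per-method mean PA,
#'   SE of PA over replicates, mean MSE, gain ratio vs GBLUP), `pa` and
#'   `mse` per-replicate matrices, pooled `spearman` and `agreement`
#'   matrices, and the failed-replicate log.
#' @export
run_experiment <- function(geno, ystar, plan = NULL,
                           variants = .VARIANTS,
                           meta_kinds = NULL,
                           learners = base_learner_set(),
                           k_inner = 5, n_reps = 10, frac = 0.7,
                           seed = 1, trait = NULL) {
  X <- if (inherits(geno, "genotype_matrix")) geno$dosage else as.matrix(geno)
  if (anyNA(X)) stop("genotypes contain missing values; run impute_missing()")
  if (inherits(ystar, "adjusted_phenotypes")) {
    if (is.null(trait)) trait <- ystar$trait[1]
    ystar <- stats::setNames(ystar$y_star, ystar$id)
  }
  if (is.null(trait)) trait <- "trait"
  ids <- intersect(rownames(X), names(ystar))
  if (length(ids) < 10) stop("fewer than 10 individuals with both genotype ",
                             "and adjusted phenotype")
  X <- X[ids, , drop = FALSE]
  y <- ystar[ids]
  n <- length(ids)
  set.seed(seed)
  if (is.null(plan)) plan <- make_splits(n, frac = frac, n_reps = n_reps)
  variants <- match.arg(variants, .VARIANTS, several.ok = TRUE)

  lnames <- vapply(learners, `[[`, character(1), "name")
  meta_labels <- unlist(lapply(variants, function(v) {
    kinds <- if (is.null(meta_kinds)) .meta_kinds_for(v)
             else intersect(meta_kinds, .meta_kinds_for(v))
    vapply(kinds, .method_label, character(1), variant = v)
  }))
  methods <- c(lnames, meta_labels)

  pa_mat <- matrix(NA_real_, plan$n_reps, length(methods),
                   dimnames = list(NULL, methods))
  mse_mat <- pa_mat
  pooled <- stats::setNames(
    lapply(methods, function(m) numeric(0)), methods)
  pooled_obs <- numeric(0)
  failures <- character(0)
  rep_seeds <- sample.int(2^31 - 2, plan$n_reps)

  for (r in seq_len(plan$n_reps)) {
    res <- tryCatch({
      tr <- plan$reps[[r]]$train
      te <- plan$reps[[r]]$test
      set.seed(rep_seeds[r])
      L0 <- generate_level_one(learners, X[tr, , drop = FALSE], y[tr],
                               k_inner = k_inner)
      mc <- center_markers(X[tr, , drop = FALSE])
      snp <- list(W = mc$W, p = mc$p, denom = mc$denom)
      preds <- list()
      Zt <- base_predictions(L0, X[te, , drop = FALSE])
      for (m in colnames(Zt)) preds[[m]] <- Zt[, m]
      for (v in variants) {
        kinds <- if (is.null(meta_kinds)) .meta_kinds_for(v)
                 else intersect(meta_kinds, .meta_kinds_for(v))
        Lv <- build_metadata(L0, v, snp = snp)
        for (kind in kinds) {
          meta <- fit_meta(kind, Lv)
          preds[[.method_label(kind, v)]] <-
            predict_stack(meta, Lv, X[te, , drop = FALSE])
        }
      }
      list(preds = preds, te = te)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("replicate %d: %s", r,
                                      conditionMessage(res)))
      next
    }
    obs <- y[res$te]
    for (m in names(res$preds)) {
      pa_mat[r, m] <- suppressWarnings(predictive_ability(res$preds[[m]],
                                                          obs))
      mse_mat[r, m] <- mse(res$preds[[m]], obs)
      pooled[[m]] <- c(pooled[[m]], res$preds[[m]])
    }
    pooled_obs <- c(pooled_obs, obs)
  }
  if (all(is.na(pa_mat)))
    stop("every replicate failed: ", paste(failures, collapse = "; "))

  mean_pa <- colMeans(pa_mat, na.rm = TRUE)
  se_pa <- apply(pa_mat, 2, function(v)
    stats::sd(v, na.rm = TRUE) / sqrt(sum(!is.na(v))))
  mean_mse <- colMeans(mse_mat, na.rm = TRUE)
  gain <- if ("GBLUP" %in% methods)
    100 * mean_pa / mean_pa[["GBLUP"]] else rep(NA_real_, length(methods))

  keep <- lengths(pooled) > 0
  Pm <- do.call(cbind, pooled[keep])
  spearman <- stats::cor(Pm, method = "spearman")
  agreement <- matrix(1, ncol(Pm), ncol(Pm),
                      dimnames = dimnames(spearman))
  for (i in seq_len(ncol(Pm)))
    for (j in seq_len(ncol(Pm)))
      agreement[i, j] <- top_decile_agreement(Pm[, i], Pm[, j])

  summary_df <- data.frame(trait = trait, method = methods,
                           mean_pa = as.numeric(mean_pa),
                           se_pa = as.numeric(se_pa),
                           mean_mse = as.numeric(mean_mse),
                           gain_vs_gblup_pct = as.numeric(gain),
                           stringsAsFactors = FALSE)
  structure(list(summary = summary_df, pa = pa_mat, mse = mse_mat,
                 spearman = spearman, agreement = agreement,
                 pooling = "test predictions pooled over replicates",
                 plan = plan, trait = trait, seed = seed,
                 failures = failures),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("stacking evaluation report (trait:", x$trait, ")\n")
  s <- x$summary[order(-x$summary$mean_pa), ]
  cat(sprintf("  %-14s %8s %8s %10s %8s\n",
              "method", "PA", "SE", "MSE", "gain%"))
  for (i in seq_len(min(nrow(s), 12)))
    cat(sprintf("  %-14s %8.3f %8.3f %10.4g %8.1f\n",
                s$method[i], s$mean_pa[i], s$se_pa[i], s$mean_mse[i],
                s$gain_vs_gblup_pct[i]))
  if (nrow(s) > 12) cat("  ... (", nrow(s) - 12, "more )\n")
  if (length(x$failures)) cat("  failed replicates:",
                              length(x$failures), "\n")
  invisible(x)
}

#' Write an evaluation report to CSV and JSON files
#'
#' Emits `summary.csv`, per-replicate `pa.csv` and `mse.csv`, the pooled
#' `spearman.csv` and `agreement.csv` matrices, and a `report.json` with
#' the scalar metadata. Output is deterministic: two runs with the same
#' master seed produce byte-identical files.
#'
#' @param report an `eval_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_eval_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(report$summary, file.path(dir, "summary.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(report$pa), file.path(dir, "pa.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(report$mse), file.path(dir, "mse.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(as.data.frame(report$spearman),
                   file.path(dir, "spearman.csv"), quote = FALSE)
  utils::write.csv(as.data.frame(report$agreement),
                   file.path(dir, "agreement.csv"), quote = FALSE)
  jsonlite::write_json(
    list(trait = report$trait, seed = report$seed,
         n_reps = report$plan$n_reps, n_train = report$plan$n_train,
         n_test = report$plan$n_test, pooling = report$pooling,
         failures = report$failures),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}
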