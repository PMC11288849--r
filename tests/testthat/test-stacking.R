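# a deterministic "oracle" learner that always returns the true response,
# and a constant learner, for plumbing checks
oracle_learner <- function(y_full) {
  base_learner("oracle",
               fit = function(X, y) y_full,
               predict = function(engine, Xnew) engine[rownames(Xnew)])
}
constant_learner <- function(name, value) {
  base_learner(name,
               fit = function(X, y) value,
               predict = function(engine, Xnew) rep(engine, nrow(Xnew)))
}

test_that("out-of-fold metadata passes an oracle learner through intact", {
  X <- toy_dosage(n = 20, m = 10, seed = 1)
  y <- stats::setNames(rnorm(20), rownames(X))
  L <- generate_level_one(list(oracle_learner(y), constant_learner("c", 2)),
                          X, y, k_inner = 5, seed = 3)
  expect_equal(unname(L$Z[, "oracle"]), unname(y))
  expect_equal(unname(L$inner_pa[["oracle"]]), 1)
  expect_true(is.na(L$inner_pa[["c"]]))  # constant column, undefined PA
  # leave-one-out boundary: every row predicted once
  L2 <- generate_level_one(list(oracle_learner(y)), X[1:10, ], y[1:10],
                           k_inner = 10, seed = 4)
  expect_false(anyNA(L2$Z))
})

test_that("level-one generation is deterministic and drops failing learners", {
  X <- toy_dosage(n = 24, m = 12, seed = 2)
  y <- stats::setNames(as.numeric(X %*% rnorm(12, 0, .4)) + rnorm(24),
                       rownames(X))
  lrn <- list(base_learner("GBLUP", selstack:::.gblup_learner_fit,
                           selstack:::.gblup_learner_predict),
              constant_learner("c", 1))
  L1 <- generate_level_one(lrn, X, y, seed = 11)
  L2 <- generate_level_one(lrn, X, y, seed = 11)
  expect_identical(L1$Z, L2$Z)
  bad <- base_learner("boom", fit = function(X, y) stop("nope"),
                      predict = function(e, X) NULL)
  expect_warning(L3 <- generate_level_one(c(lrn, list(bad)), X, y, seed = 1),
                 "boom")
  expect_false("boom" %in% colnames(L3$Z))
})

test_that("the best-learner rule keeps strictly-above-mean performers", {
  expect_equal(select_best(c(A = 0.10, B = 0.20, C = 0.30)), "C")
  expect_equal(select_best(c(A = 0.0, B = 0.4)), "B")
  expect_warning(sel <- select_best(c(A = 0.15, B = 0.15, C = 0.15)),
                 "keeping all")
  expect_equal(sel, c("A", "B", "C"))
  expect_error(select_best(c(A = NA_real_, B = NA_real_)), "finite")
  expect_warning(sel2 <- select_best(c(A = 0.1, B = 0.3, C = NA)), "undefined")
  expect_equal(sel2, "B")
})

test_that("metadata variants subset columns and attach the SNP block", {
  X <- toy_dosage(n = 20, m = 8, seed = 5)
  y <- stats::setNames(rnorm(20), rownames(X))
  lrn <- list(oracle_learner(y), constant_learner("c1", 1),
              constant_learner("c2", 2))
  L <- suppressWarnings(generate_level_one(lrn, X, y, seed = 2))
  mc <- center_markers(X)
  snp <- list(W = mc$W, p = mc$p, denom = mc$denom)
  v1 <- build_metadata(L, "GEBV-BL")
  expect_equal(ncol(v1$Z), 3)
  expect_null(v1$snp_W)
  v2 <- build_metadata(L, "GEBV-BL+SNP", snp = snp)
  expect_equal(ncol(v2$snp_W), 8)
  v3 <- suppressWarnings(build_metadata(L, "GEBV-BL-Best"))
  expect_equal(colnames(v3$Z), "oracle")  # only finite + above-mean learner
  expect_error(build_metadata(L, "GEBV-BL+SNP"), "SNP block")
  Lx <- L; Lx$inner_pa <- rep(NA_real_, 3)
  expect_error(build_metadata(Lx, "GEBV-BL-Best"), "absent")
})

test_that("SSM over duplicated learners equals the learner itself", {
  X <- toy_dosage(n = 18, m = 6, seed = 7)
  y <- stats::setNames(rnorm(18), rownames(X))
  lrn <- list(oracle_learner(y),
              base_learner("oracle2", fit = function(X, yy) y,
                           predict = function(e, Xn) e[rownames(Xn)]))
  L <- generate_level_one(lrn, X, y, seed = 1)
  meta <- fit_meta("SSM", L)
  pred <- predict_stack(meta, L, X)
  expect_equal(unname(pred), unname(y))
  # constants are conserved
  Lc <- generate_level_one(list(constant_learner("a", 3),
                                constant_learner("b", 3)), X, y, seed = 1)
  metac <- fit_meta("SSM", Lc)
  expect_equal(unname(predict_stack(metac, Lc, X[1:4, ])), rep(3, 4))
})

test_that("SR recalibrates a single perfect learner to the identity", {
  X <- toy_dosage(n = 25, m = 6, seed = 9)
  y <- stats::setNames(rnorm(25), rownames(X))
  L <- generate_level_one(list(oracle_learner(y)), X, y, seed = 2)
  meta <- fit_meta("SR", L)
  expect_equal(unname(meta$fit$beta), c(0, 1), tolerance = 1e-8)
  expect_equal(unname(predict_stack(meta, L, X)), unname(y), tolerance = 1e-8)
  # collinear columns fall back to the pseudo-inverse with a warning
  lrn2 <- list(oracle_learner(y),
               base_learner("copy", fit = function(X, yy) y,
                            predict = function(e, Xn) e[rownames(Xn)]))
  L2 <- generate_level_one(lrn2, X, y, seed = 2)
  expect_warning(meta2 <- fit_meta("SR", L2), "pseudo-inverse")
  expect_equal(unname(predict_stack(meta2, L2, X)), unname(y),
               tolerance = 1e-6)
})

test_that("SWR weights are non-negative, sum to one, and favor the oracle", {
  X <- toy_dosage(n = 30, m = 8, seed = 12)
  y <- stats::setNames(rnorm(30), rownames(X))
  lrn <- list(oracle_learner(y), constant_learner("noise", 0.5))
  L <- generate_level_one(lrn, X, y, seed = 3)
  meta <- fit_meta("SWR", L)
  expect_true(all(meta$fit$w >= 0))
  expect_equal(sum(meta$fit$w), 1)
  expect_gt(meta$fit$w[1], 0.9)
})

test_that("ridge meta-learner shrinks to the training mean as penalty grows", {
  X <- toy_dosage(n = 26, m = 10, seed = 13)
  y <- stats::setNames(as.numeric(X %*% rnorm(10, 0, .4)) + rnorm(26),
                       rownames(X))
  L <- generate_level_one(list(oracle_learner(y), constant_learner("c", 1)),
                          X, y, seed = 5)
  meta_inf <- fit_meta("SRR", L, lambda = Inf)
  expect_equal(unname(predict_stack(meta_inf, L, X)),
               rep(mean(y), 26), tolerance = 1e-8)
  # CV-chosen penalty beats infinite shrinkage in training fit
  meta_cv <- fit_meta("SRR", L)
  expect_true(is.finite(meta_cv$fit$lambda))
})

test_that("meta predictions are invariant to learner column order", {
  X <- toy_dosage(n = 24, m = 8, seed = 17)
  y <- stats::setNames(as.numeric(X %*% rnorm(8, 0, .4)) + rnorm(24),
                       rownames(X))
  mkL <- function(swap) {
    lrn <- list(oracle_learner(y), constant_learner("c", 2))
    if (swap) lrn <- rev(lrn)
    generate_level_one(lrn, X, y, seed = 6)
  }
  L1 <- mkL(FALSE); L2 <- mkL(TRUE)
  for (kind in c("SSM", "SR")) {
    p1 <- predict_stack(suppressWarnings(fit_meta(kind, L1)), L1, X)
    p2 <- predict_stack(suppressWarnings(fit_meta(kind, L2)), L2, X)
    expect_equal(p1, p2, tolerance = 1e-8)
  }
})

test_that("S2KGBLUP demands a SNP variant and predicts finitely end-to-end", {
  sim <- small_sim()
  g <- impute_missing(sim$genotypes)
  X <- g$dosage
  ids <- rownames(X)
  tr <- ids[1:45]; te <- ids[46:60]
  y <- stats::setNames(
    sim$truth$genetic_value + rnorm(length(ids), 0, 0.5), ids)
  lrn <- base_learner_set(n_trees = 40)[c(1, 2, 14)]  # GBLUP, MARS1, RF
  L <- generate_level_one(lrn, X[tr, ], y[tr], seed = 9)
  mc <- center_markers(X[tr, ])
  snp <- list(W = mc$W, p = mc$p, denom = mc$denom)
  expect_error(fit_meta("S2KGBLUP", build_metadata(L, "GEBV-BL")), "SNP")
  Lv <- build_metadata(L, "GEBV-BL+SNP", snp = snp)
  meta <- fit_meta("S2KGBLUP", Lv)
  pred <- predict_stack(meta, Lv, X[te, ])
  expect_length(pred, 15)
  expect_true(all(is.finite(pred)))
  expect_gt(cor(pred, sim$truth$genetic_value[46:60]), 0)
  # variant mismatch between fit and predict is a hard error
  expect_error(predict_stack(meta, L, X[te, ]), "variant mismatch")
})

test_that("a pure-noise extra learner shifts SSM by exactly its share", {
  X <- toy_dosage(n = 20, m = 6, seed = 19)
  y <- stats::setNames(rnorm(20), rownames(X))
  set.seed(4)
  noise_vals <- rnorm(20)
  noise <- base_learner("noise",
                        fit = function(X, yy) stats::setNames(noise_vals,
                                                              rownames(X)),
                        predict = function(e, Xn) e[rownames(Xn)])
  L1 <- generate_level_one(list(oracle_learner(y)), X, y, seed = 2)
  L2 <- generate_level_one(list(oracle_learner(y), noise), X, y, seed = 2)
  p1 <- predict_stack(fit_meta("SSM", L1), L1, X)
  p2 <- predict_stack(fit_meta("SSM", L2), L2, X)
  expect_equal(unname(p2), unname((p1 + noise_vals) / 2), tolerance = 1e-10)
})
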