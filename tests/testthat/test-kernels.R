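test_that("marker centering follows the 2-2p / 1-2p / -2p coding", {
  X <- matrix(c(2, 0,
                0, 2,
                1, 1), 3, 2, byrow = TRUE)
  mc <- center_markers(X)
  expect_equal(mc$p, c(0.5, 0.5))
  expect_equal(mc$W[1, ], c(1, -1))    # dosage 2 -> 2 - 2p = 1 at p = 0.5
  expect_equal(mc$W[3, ], c(0, 0))     # heterozygote -> 1 - 2p = 0
  expect_equal(mc$denom, 1)
  # a column of dosages (0,1,2) centers to (-1,0,1)
  mc2 <- center_markers(matrix(c(0, 1, 2), 3, 1))
  expect_equal(as.numeric(mc2$W), c(-1, 0, 1))
  # external (training) frequencies are used verbatim
  mc3 <- center_markers(matrix(c(0, 1, 2), 3, 1), freqs = 0.25)
  expect_equal(as.numeric(mc3$W), c(-0.5, 0.5, 1.5))
  expect_error(center_markers(matrix(c(2, 2, 2), 3, 1)), "monomorphic")
  expect_error(center_markers(matrix(c(NA, 1, 2), 3, 1)), "missing")
})

test_that("VanRaden G matches the hand-computed 3x2 example", {
  X <- matrix(c(0, 2,
                1, 1,
                2, 0), 3, 2, byrow = TRUE)
  K <- grm_vanraden(center_markers(X))$K
  expect_equal(unname(K),
               matrix(c(2, 0, -2, 0, 0, 0, -2, 0, 2), 3, 3), tolerance = 1e-12)
})

test_that("VanRaden G equals an element-wise double-loop oracle", {
  set.seed(13)
  X <- toy_dosage(n = 10, m = 50, seed = 13)
  mc <- center_markers(X)
  K <- grm_vanraden(mc)$K
  oracle <- matrix(0, 10, 10)
  for (i in 1:10) for (k in 1:10)
    oracle[i, k] <- sum(mc$W[i, ] * mc$W[k, ]) / mc$denom
  expect_equal(unname(K), oracle, tolerance = 1e-10)
  # duplicated individual gives identical rows/columns
  X2 <- rbind(X, X[1, , drop = FALSE])
  rownames(X2)[11] <- "dup"
  K2 <- grm_vanraden(center_markers(X2))$K
  expect_equal(unname(K2["dup", ]), unname(K2["T01", ]))
  # centering identity: every row of G sums to zero
  expect_lt(max(abs(rowSums(K))), 1e-8 * ncol(X))
})

test_that("prediction kernels standardize columns and handle degeneracies", {
  set.seed(4)
  v <- rnorm(8); v <- (v - mean(v)) / sqrt(mean((v - mean(v))^2))
  K <- grm_from_predictions(matrix(v, 8, 1))
  expect_equal(unname(K$K), tcrossprod(v), tolerance = 1e-12)
  # duplicated columns leave the kernel unchanged
  P <- matrix(rnorm(16), 8, 2) %*% diag(c(3, 0.5)) + 5
  K1 <- grm_from_predictions(cbind(P[, 1], P[, 1]))
  K2 <- grm_from_predictions(P[, 1, drop = FALSE])
  expect_equal(K1$K, K2$K, tolerance = 1e-12)
  # orthonormal columns times sqrt(n) give unit mean diagonal
  q <- qr.Q(qr(matrix(rnorm(64), 8)))[, 1:2]
  q <- sweep(q, 2, colMeans(q))  # mean-zero orthogonal directions
  Ko <- grm_from_predictions(q * sqrt(8))
  expect_equal(mean(diag(Ko$K)), 1, tolerance = 1e-10)
  expect_warning(grm_from_predictions(cbind(P[, 1], rep(2, 8))), "constant")
  expect_error(grm_from_predictions(matrix(1, 8, 2)), "constant")
})

test_that("GBLUP with fixed variances reproduces the MME closed form", {
  # K = I, var_g = var_e = 1, b fixed at 0 by symmetry: u = (I + I)^-1 y
  y <- stats::setNames(c(1, -1), c("a", "b"))
  gb <- fit_gblup(y, diag(2), var_g = 1, var_e = 1)
  expect_equal(unname(gb$u), c(0.5, -0.5), tolerance = 1e-10)
  # no genetic variance, no signal
  gb0 <- fit_gblup(y, diag(2), var_g = 0, var_e = 1)
  expect_equal(unname(gb0$u), c(0, 0))
  expect_error(fit_gblup(y, matrix(c(1, 2, 2, 1), 2, 2)), "definite")
})

test_that("GBLUP GEBVs equal the matched-penalty marker-ridge solution", {
  set.seed(42)
  for (rep in 1:3) {
    n <- sample(30:80, 1); m <- sample(60:200, 1)
    X <- toy_dosage(n = n, m = m, seed = 42 + rep)
    y <- stats::setNames(as.numeric(X %*% rnorm(m, 0, 0.1) + rnorm(n)),
                         rownames(X))
    mc <- center_markers(X)
    gb <- fit_gblup(y, grm_vanraden(mc))
    lam <- mc$denom * gb$var_e / gb$var_g
    alpha <- solve(crossprod(mc$W) + diag(lam, m),
                   crossprod(mc$W, y - gb$b))
    expect_equal(unname(gb$u), as.numeric(mc$W %*% alpha), tolerance = 1e-6)
  }
})

test_that("GBLUP estimates are invariant to sample reordering", {
  set.seed(7)
  X <- toy_dosage(n = 20, m = 40, seed = 7)
  y <- stats::setNames(rnorm(20), rownames(X))
  gb1 <- fit_gblup(y, grm_vanraden(center_markers(X)))
  ord <- sample(20)
  gb2 <- fit_gblup(y[ord], grm_vanraden(center_markers(X[ord, ])))
  expect_equal(gb2$var_g, gb1$var_g, tolerance = 1e-8)
  expect_equal(gb2$u[names(gb1$u)], gb1$u, tolerance = 1e-8)
})

test_that("kernel prediction extends GEBVs consistently", {
  set.seed(19)
  X <- toy_dosage(n = 30, m = 60, seed = 19)
  y <- stats::setNames(as.numeric(X %*% rnorm(60, 0, 0.1) + rnorm(30, 0, .5)),
                       rownames(X))
  train <- rownames(X)[1:24]; test <- rownames(X)[25:30]
  mc <- center_markers(X[train, ])
  Wf <- sweep(X, 2, 2 * mc$p)
  Kf <- tcrossprod(Wf) / mc$denom
  gb <- fit_gblup(y[train], Kf[train, train])
  pred <- predict_gblup(gb, Kf, test)
  # oracle: solve the whole-data MME treating test phenotypes as unknown;
  # equivalently the conditional mean of u_test given u_train under K
  oracle <- Kf[test, train] %*% solve(Kf[train, train] +
                                        diag(1e-8, 24), gb$u)
  expect_equal(unname(pred), as.numeric(oracle), tolerance = 1e-10)
  # duplicate of a training individual predicts that individual's GEBV
  K2 <- Kf[c(train, train[1]), c(train, train[1])]
  rownames(K2)[25] <- colnames(K2)[25] <- "copy"
  expect_equal(unname(predict_gblup(gb, K2, "copy")), unname(gb$u[1]),
               tolerance = 1e-5)
  # unrelated test block carries no information
  Kb <- diag(0.5, 26); Kb[1:24, 1:24] <- Kf[train, train]
  dimnames(Kb) <- list(c(train, "u1", "u2"), c(train, "u1", "u2"))
  expect_equal(unname(predict_gblup(gb, Kb, c("u1", "u2"))), c(0, 0),
               tolerance = 1e-8)
  expect_error(predict_gblup(gb, Kf, "nobody"), "missing")
})

test_that("whole-data MME oracle matches kernel-extended prediction", {
  # fitting on all data with test responses treated as missing is the
  # textbook BLUP extension; compare against an explicit V-based solve
  set.seed(23)
  X <- toy_dosage(n = 30, m = 80, seed = 23)
  y <- stats::setNames(as.numeric(X %*% rnorm(80, 0, 0.1) + rnorm(30, .3)),
                       rownames(X))
  train <- rownames(X)[1:22]; test <- rownames(X)[23:30]
  mc <- center_markers(X[train, ])
  Wf <- sweep(X, 2, 2 * mc$p)
  Kf <- tcrossprod(Wf) / mc$denom
  gb <- fit_gblup(y[train], Kf[train, train])
  pred <- predict_gblup(gb, Kf, test)
  Vtt <- gb$var_g * Kf[train, train] + diag(gb$var_e, 22)
  oracle <- gb$var_g * Kf[test, train] %*% solve(Vtt, y[train] - gb$b)
  expect_equal(unname(pred), as.numeric(oracle), tolerance = 1e-6)
})

test_that("two-kernel GBLUP satisfies its nesting and collinearity identities", {
  set.seed(42)
  X <- matrix(rbinom(50 * 200, 2, 0.4), 50, 200,
              dimnames = list(sprintf("I%02d", 1:50), NULL))
  y <- stats::setNames(as.numeric(X %*% rnorm(200, 0, 0.1) + rnorm(50)),
                       rownames(X))
  K <- grm_vanraden(center_markers(X))
  gb <- fit_gblup(y, K)
  # K2 = K1: total prediction equals single-kernel fit at the summed variance
  m2k <- fit_two_kernel_gblup(y, K, K)
  gbs <- fit_gblup(y, K, var_g = m2k$var1 + m2k$var2, var_e = m2k$var_e)
  expect_equal(unname(m2k$u1 + m2k$u2), unname(gbs$u), tolerance = 1e-6)
  expect_equal(m2k$var1 + m2k$var2, gb$var_g, tolerance = 1e-2)
  # all variances pinned: reduces algebraically to the single-kernel fit
  m2k0 <- fit_two_kernel_gblup(y, K, K, var1 = gb$var_g, var2 = 1e-12,
                               var_e = gb$var_e)
  expect_equal(unname(m2k0$u1 + m2k0$u2), unname(gb$u), tolerance = 1e-5)
})

test_that("two independent kernel variances are recovered on average", {
  recov <- sapply(1:6, function(s) {
    set.seed(300 + s)
    n <- 100
    A <- tcrossprod(matrix(rnorm(n * n), n)) / n
    B <- tcrossprod(matrix(rnorm(n * n), n)) / n
    u1 <- t(chol(A + diag(1e-8, n))) %*% rnorm(n)
    u2 <- t(chol(B + diag(1e-8, n))) %*% rnorm(n) * sqrt(0.5)
    yy <- stats::setNames(as.numeric(1 + u1 + u2 + rnorm(n, 0, 0.8)),
                          paste0("i", 1:n))
    dimnames(A) <- dimnames(B) <- list(names(yy), names(yy))
    f <- fit_two_kernel_gblup(yy, A, B)
    c(f$var1, f$var2)
  })
  expect_equal(mean(recov[1, ]), 1.0, tolerance = 0.3)
  expect_equal(mean(recov[2, ]), 0.5, tolerance = 0.3)
})
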