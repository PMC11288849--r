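# balanced one-way ANOVA gives closed-form REML estimates:
# sigma_e2 = MSE, sigma_g2 = (MSB - MSE) / k  (k replicates per group)
anova_reml_oracle <- function(y, grp) {
  k <- table(grp)[1]
  msb <- stats::anova(stats::lm(y ~ grp))["grp", "Mean Sq"]
  mse <- stats::anova(stats::lm(y ~ grp))["Residuals", "Mean Sq"]
  c(g = max((msb - mse) / k, 0), e = mse)
}

test_that("EM-REML matches the closed-form balanced one-way oracle", {
  set.seed(31)
  n_grp <- 8; k <- 6
  grp <- rep(sprintf("F%02d", 1:n_grp), each = k)
  y <- rnorm(n_grp)[as.integer(factor(grp))] * 1.2 + rnorm(n_grp * k, 0, 0.8)
  rec <- pheno_records(data.frame(
    id = sprintf("i%03d", seq_along(y)), progeny = grp, year = "Y1",
    trait = "t", value = y))
  vc <- suppressWarnings(fit_vc_reml(rec, tol = 1e-12))
  oracle <- anova_reml_oracle(y, factor(grp))
  expect_equal(unname(vc$components["sigma_g2"]), unname(oracle["g"]),
               tolerance = 1e-6)
  expect_equal(unname(vc$components["sigma_e2"]), unname(oracle["e"]),
               tolerance = 1e-6)
})

test_that("EM-REML agrees with lme4 on a crossed two-factor design", {
  skip_if_not_installed("lme4")
  rec <- simulate_vc_records(n_progenies = 10, fam_size = 6, n_years = 3,
                             components = c(sigma_g2 = 1.5, sigma_p2 = 0.5,
                                            sigma_r2 = 0, sigma_b2 = 0,
                                            sigma_i2 = 0.3, sigma_e2 = 1),
                             n_plots = 0, seed = 77)
  vc <- suppressWarnings(fit_vc_reml(rec, tol = 1e-10))
  fm <- lme4::lmer(value ~ 0 + year + (1 | progeny) + (1 | id) +
                     (1 | year:progeny), data = as.data.frame(rec),
                   REML = TRUE,
                   control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                               check.nobs.vs.nRE = "ignore"))
  vl <- as.data.frame(lme4::VarCorr(fm))
  get <- function(g) vl$vcov[vl$grp == g]
  expect_equal(unname(vc$components["sigma_g2"]), get("progeny"),
               tolerance = 1e-3)
  expect_equal(unname(vc$components["sigma_p2"]), get("id"),
               tolerance = 1e-3)
  expect_equal(unname(vc$components["sigma_i2"]), get("year:progeny"),
               tolerance = 1e-3)
  expect_equal(unname(vc$components["sigma_e2"]), get("Residual"),
               tolerance = 1e-3)
})

test_that("variance parameters are recovered on average across seeds", {
  ests <- sapply(1:8, function(s) {
    rec <- simulate_vc_records(components = c(sigma_g2 = 1, sigma_p2 = 0,
                                              sigma_r2 = 0, sigma_b2 = 0,
                                              sigma_i2 = 0, sigma_e2 = 1),
                               n_plots = 0, seed = 400 + s)
    vc <- suppressWarnings(fit_vc_reml(rec))
    vc$components[c("sigma_g2", "sigma_e2")]
  })
  expect_equal(mean(ests["sigma_g2", ]), 1, tolerance = 0.2)
  expect_equal(mean(ests["sigma_e2", ]), 1, tolerance = 0.2)
})

test_that("REML log-likelihood is non-decreasing over EM iterations", {
  rec <- simulate_vc_records(n_progenies = 8, fam_size = 5, n_years = 2,
                             seed = 5)
  vc <- suppressWarnings(fit_vc_reml(rec, maxit = 200))
  expect_true(all(diff(vc$loglik) > -1e-6))
})

test_that("degenerate inputs: constant records floor all components", {
  rec <- pheno_records(data.frame(id = rep(sprintf("i%d", 1:20), 2),
                                  progeny = rep(rep(c("A", "B"), each = 10), 2),
                                  year = rep(c("Y1", "Y2"), each = 20),
                                  trait = "t", value = 5))
  vc <- suppressWarnings(fit_vc_reml(rec))
  comp <- vc$components[!is.na(vc$components)]
  expect_true(all(comp <= 1e-8))
})

test_that("heritability follows the printed formula (plot term excluded)", {
  vc <- c(sigma_g2 = 1, sigma_p2 = 1, sigma_r2 = 1, sigma_b2 = 99,
          sigma_i2 = 0, sigma_e2 = 1)
  expect_equal(heritability(vc), 0.25)
  expect_equal(heritability(c(sigma_g2 = 0.3, sigma_p2 = 0, sigma_r2 = 0,
                              sigma_b2 = 5, sigma_i2 = 0.1, sigma_e2 = 0.6)),
               0.3)
  expect_equal(heritability(c(sigma_g2 = 0, sigma_p2 = 1, sigma_r2 = 0,
                              sigma_b2 = 0, sigma_i2 = 0, sigma_e2 = 1)), 0)
  # include_plot switch widens the denominator
  expect_equal(heritability(vc, include_plot = TRUE), 1 / 103)
  expect_error(heritability(c(sigma_g2 = 0, sigma_p2 = 0, sigma_r2 = 0,
                              sigma_b2 = 0, sigma_i2 = 0, sigma_e2 = 0)),
               "zero")
  # h2 in [0,1] for any non-negative components
  set.seed(2)
  for (i in 1:25) {
    v <- stats::setNames(runif(6), c("sigma_g2", "sigma_p2", "sigma_r2",
                                     "sigma_b2", "sigma_i2", "sigma_e2"))
    h <- heritability(v)
    expect_gte(h, 0); expect_lte(h, 1)
  }
})

test_that("adjustment removes exactly year, plot and year-progeny effects", {
  # single year, single plot: y* reduces to the record minus the year mean
  set.seed(8)
  y <- rnorm(24)
  rec <- pheno_records(data.frame(
    id = sprintf("i%02d", 1:24), progeny = rep(c("A", "B", "C"), each = 8),
    year = "Y1", trait = "t", value = y))
  vc <- suppressWarnings(fit_vc_reml(rec))
  adj <- adjust_phenotypes(rec, vc)
  expect_equal(adj$y_star[match(rec$id, adj$id)], y - vc$beta[["Y1"]],
               tolerance = 1e-10)
  # balanced design: the fixed year solution is the arithmetic year mean
  expect_equal(unname(vc$beta[["Y1"]]), mean(y), tolerance = 1e-6)
  expect_equal(attr(adj, "provenance"), c("year", "plot", "year_progeny"))
})

test_that("adjusted phenotypes track genetic values better than raw means", {
  sim <- small_sim()
  cfg <- sim$cfg
  cfg$h2 <- 0.5
  wins <- sapply(1:6, function(s) {
    tr <- simulate_trials(sim$genotypes, sim$architecture, cfg,
                          seed = 600 + s)
    vc <- suppressWarnings(fit_vc_reml(tr$records))
    adj <- adjust_phenotypes(tr$records, vc)
    gv <- tr$truth$genetic_value[match(adj$id, tr$truth$id)]
    raw <- tapply(tr$records$value, tr$records$id, mean)[adj$id]
    cor(adj$y_star, gv) >= cor(as.numeric(raw), gv)
  })
  expect_gte(sum(wins), 4)
})

test_that("single-level and unreplicated terms are dropped with a warning", {
  rec <- simulate_vc_records(n_progenies = 6, fam_size = 5, n_years = 1,
                             components = c(sigma_g2 = 1, sigma_p2 = 0,
                                            sigma_r2 = 0, sigma_b2 = 0,
                                            sigma_i2 = 0, sigma_e2 = 1),
                             n_plots = 0, seed = 2)
  expect_warning(vc <- fit_vc_reml(rec), "dropped")
  expect_true(all(c("p", "i") %in% vc$dropped))  # no repeats, single year
  expect_true(is.na(vc$components["sigma_p2"]))
})
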