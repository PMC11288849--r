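#' Configuration for the synthetic progeny-trial simulator
#'
#' The defaults emulate a full-sib coffee progeny trial: 13 progenies of 15
#' individuals (195 total) derived from crosses between two pools of three
#' founder parents, genotyped for biallelic SNPs spread over 11 chromosomes,
#' and phenotyped over 3 years in a plot-structured field.
#'
#' @param n_progenies number of full-sib families (default 13).
#' @param fam_size individuals per family (default 15).
#' @param n_markers number of biallelic SNP markers (default 1000).
#' @param n_chromosomes number of chromosomes markers are spread over.
#' @param chrom_length_cM genetic length of each chromosome in centimorgans;
#'   0 makes every marker on a chromosome co-segregate.
#' @param maf_range range of founder alt-allele frequencies (uniform draw).
#' @param n_qtl number of causal markers.
#' @param shares length-3 non-negative vector of genetic-variance shares
#'   (additive, dominance, pairwise epistasis); must sum to 1.
#' @param genetic_var total genetic variance the simulated genetic values are
#'   scaled to (trait units squared).
#' @param h2 optional target heritability on the progeny-model scale (the
#'   ratio of between-family genetic variance to phenotypic variance, plot
#'   variance excluded from the denominator). When set, the residual-type
#'   variances are solved to hit it; when `NULL`, `vc` is used as given.
#' @param vc named list of nuisance variance components
#'   `sigma_p2` (extra permanent environment), `sigma_r2` (population),
#'   `sigma_b2` (plot), `sigma_i2` (year-by-progeny), `sigma_e2` (residual).
#' @param n_years number of evaluation years (default 3).
#' @param n_plots number of field plots individuals are grouped into.
#' @param mu overall trait mean.
#' @param year_sd standard deviation of the fixed year means around `mu`.
#' @param trait trait label attached to the records.
#' @param seed master seed; stage-specific child seeds are derived from it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_progenies = 13, fam_size = 15, n_markers = 1000,
                       n_chromosomes = 11, chrom_length_cM = 100,
                       maf_range = c(0.05, 0.5), n_qtl = 100,
                       shares = c(additive = 1, dominance = 0, epistasis = 0),
                       genetic_var = 1, h2 = NULL,
                       vc = list(sigma_p2 = 0, sigma_r2 = 0, sigma_b2 = 0.1,
                                 sigma_i2 = 0.1, sigma_e2 = 1),
                       n_years = 3, n_plots = 15, mu = 10, year_sd = 1,
                       trait = "trait", seed = 1) {
  shares <- as.numeric(shares)
  if (length(shares) != 3 || any(shares < 0) ||
      abs(sum(shares) - 1) > 1e-8)
    stop("shares must be 3 non-negative values summing to 1")
  if (any(unlist(vc) < 0)) stop("variance components must be >= 0")
  if (n_progenies * fam_size < 10)
    stop("population too small: need n_progenies * fam_size >= 10")
  structure(list(
    n_progenies = n_progenies, fam_size = fam_size, n_markers = n_markers,
    n_chromosomes = n_chromosomes, chrom_length_cM = chrom_length_cM,
    maf_range = maf_range, n_qtl = n_qtl, shares = shares,
    genetic_var = genetic_var, h2 = h2, vc = vc, n_years = n_years,
    n_plots = n_plots, mu = mu, year_sd = year_sd, trait = trait,
    seed = seed), class = "sim_config")
}

# derive reproducible child seeds from the master seed so that stages can be
# re-run in isolation
.child_seeds <- function(seed, n = 4) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(2^31 - 2, n)
}

#' Simulate a family-structured SNP population
#'
#' Six founders (two pools of three) are drawn in linkage equilibrium with
#' per-marker alt-allele frequencies uniform in `maf_range`. Full-sib
#' families are produced by crossing one parent from each pool; gametes are
#' formed per chromosome with Haldane (no-interference) recombination on an
#' evenly spaced map.
#'
#' @param cfg a [sim_config()].
#' @param seed optional seed overriding the population child stream.
#' @return a [genotype_matrix()] with family and population labels.
#' @export
simulate_population <- function(cfg, seed = NULL) {
  if (cfg$n_markers < cfg$n_chromosomes)
    stop("n_markers must be >= n_chromosomes")
  set.seed(if (is.null(seed)) .child_seeds(cfg$seed)[1] else seed)
  m <- cfg$n_markers
  p <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  # contiguous blocks of markers per chromosome, evenly spaced positions
  chrom <- rep(seq_len(cfg$n_chromosomes), length.out = m)
  chrom <- sort(chrom)
  pos <- unlist(lapply(split(seq_len(m), chrom), function(ix) {
    k <- length(ix)
    if (k == 1) cfg$chrom_length_cM / 2 else
      seq(0, cfg$chrom_length_cM, length.out = k)
  }), use.names = FALSE)
  # founder haplotypes: 6 founders x 2 haplotypes
  founders <- lapply(seq_len(6), function(f)
    matrix(stats::rbinom(2 * m, 1, rep(p, each = 2)), nrow = 2, byrow = FALSE))
  # recombination fractions between adjacent markers (Haldane)
  gamete <- function(hapmat) {
    out <- integer(m)
    for (ch in unique(chrom)) {
      ix <- which(chrom == ch)
      d <- diff(pos[ix])
      r <- 0.5 * (1 - exp(-2 * d / 100))
      sw <- c(stats::rbinom(1, 1, 0.5), stats::rbinom(length(d), 1, r))
      strand <- (cumsum(sw) %% 2) + 1
      out[ix] <- hapmat[cbind(strand, ix)]
    }
    out
  }
  pairs <- expand.grid(a = 1:3, b = 4:6)
  pairs <- pairs[rep(seq_len(nrow(pairs)),
                     length.out = cfg$n_progenies), , drop = FALSE]
  n <- cfg$n_progenies * cfg$fam_size
  dos <- matrix(0L, n, m)
  fam <- character(n)
  pop <- character(n)
  row <- 0
  for (f in seq_len(cfg$n_progenies)) {
    pa <- founders[[pairs$a[f]]]
    pb <- founders[[pairs$b[f]]]
    for (k in seq_len(cfg$fam_size)) {
      row <- row + 1
      dos[row, ] <- gamete(pa) + gamete(pb)
      fam[row] <- sprintf("F%02d", f)
      pop[row] <- sprintf("HdT%d", pairs$b[f] - 3)
    }
  }
  dimnames(dos) <- list(
    sprintf("%s_%02d", fam, unlist(lapply(seq_len(cfg$n_progenies),
                                          function(i) seq_len(cfg$fam_size)))),
    sprintf("M%04d", seq_len(m)))
  g <- genotype_matrix(dos, family = fam, population = pop)
  attr(g, "founder_freq") <- p
  attr(g, "map") <- data.frame(marker = colnames(dos), chrom = chrom, pos = pos)
  g
}

#' Simulate a genetic architecture over a genotyped population
#'
#' Samples QTL positions without replacement and draws additive effects,
#' dominance deviations and pairwise additive-by-additive epistatic effects
#' (products of mean-centered dosages), then rescales each component so the
#' realized variance shares match `cfg$shares` exactly and the total genetic
#' variance matches `cfg$genetic_var`.
#'
#' @param g a [genotype_matrix()] (complete, no missing values).
#' @param cfg a [sim_config()].
#' @param seed optional seed overriding the architecture child stream.
#' @return a list of class `genetic_architecture` with the effect table, the
#'   centering means, and per-individual component values.
#' @export
simulate_architecture <- function(g, cfg, seed = NULL) {
  if (cfg$n_qtl > ncol(g$dosage)) stop("n_qtl exceeds the number of markers")
  if (cfg$shares[3] > 0 && cfg$n_qtl < 2)
    stop("epistasis share > 0 requires n_qtl >= 2")
  set.seed(if (is.null(seed)) .child_seeds(cfg$seed)[2] else seed)
  X <- g$dosage
  n <- nrow(X)
  qtl <- sort(sample.int(ncol(X), cfg$n_qtl))
  qtl_id <- colnames(X)[qtl]
  mu_j <- colMeans(X)
  a <- stats::rnorm(cfg$n_qtl)
  d <- stats::rnorm(cfg$n_qtl)
  n_pairs <- if (cfg$n_qtl >= 2) cfg$n_qtl else 0
  ep <- if (n_pairs) {
    pr <- t(replicate(n_pairs, sample(qtl, 2)))
    data.frame(m1 = pr[, 1], m2 = pr[, 2], eff = stats::rnorm(n_pairs))
  } else data.frame(m1 = integer(), m2 = integer(), eff = numeric())

  add_val <- as.numeric(X[, qtl, drop = FALSE] %*% a)
  dom_val <- as.numeric((X[, qtl, drop = FALSE] == 1) %*% d)
  Z <- sweep(X, 2, mu_j)
  epi_val <- if (n_pairs) as.numeric(
    rowSums(Z[, ep$m1, drop = FALSE] * Z[, ep$m2, drop = FALSE] *
              rep(ep$eff, each = n))) else numeric(n)

  scale_to <- function(v, target) {
    s <- stats::var(v)
    if (target == 0) return(list(k = 0, v = numeric(length(v))))
    if (s < 1e-12) stop("degenerate genetic component; increase n_qtl or MAF")
    k <- sqrt(target / s)
    list(k = k, v = v * k)
  }
  targ <- cfg$shares * cfg$genetic_var
  sa <- scale_to(add_val, targ[1])
  sd_ <- scale_to(dom_val, targ[2])
  se <- scale_to(epi_val, targ[3])

  tab <- rbind(
    data.frame(type = "additive", marker1 = qtl_id, marker2 = NA_character_,
               effect = a * sa$k),
    data.frame(type = "dominance", marker1 = qtl_id, marker2 = NA_character_,
               effect = d * sd_$k),
    if (n_pairs) data.frame(type = "epistasis",
                            marker1 = colnames(X)[ep$m1],
                            marker2 = colnames(X)[ep$m2],
                            effect = ep$eff * se$k) else NULL)
  vals <- data.frame(id = rownames(X), additive = sa$v, dominance = sd_$v,
                     epistasis = se$v,
                     total = sa$v + sd_$v + se$v,
                     stringsAsFactors = FALSE)
  structure(list(effects = tab, qtl = qtl_id, centers = mu_j, values = vals),
            class = "genetic_architecture")
}

#' Recompute genetic values from an effect table
#'
#' Applies a `genetic_architecture` effect table to a (possibly different)
#' genotype matrix using the stored centering means for the epistatic
#' product coding.
#'
#' @param arch a `genetic_architecture`.
#' @param g a [genotype_matrix()].
#' @return data.frame of per-individual component values and their total.
#' @export
genetic_values <- function(arch, g) {
  X <- g$dosage
  tab <- arch$effects
  n <- nrow(X)
  add <- tab[tab$type == "additive", ]
  dom <- tab[tab$type == "dominance", ]
  epi <- tab[tab$type == "epistasis", ]
  av <- as.numeric(X[, add$marker1, drop = FALSE] %*% add$effect)
  dv <- as.numeric((X[, dom$marker1, drop = FALSE] == 1) %*% dom$effect)
  ev <- numeric(n)
  if (nrow(epi)) {
    Z <- sweep(X, 2, arch$centers[colnames(X)])
    ev <- as.numeric(rowSums(Z[, epi$marker1, drop = FALSE] *
                               Z[, epi$marker2, drop = FALSE] *
                               rep(epi$effect, each = n)))
  }
  data.frame(id = rownames(X), additive = av, dominance = dv, epistasis = ev,
             total = av + dv + ev, stringsAsFactors = FALSE)
}

#' Simulate multi-year trial phenotype records
#'
#' Generates one record per individual and year from the progeny-trial mixed
#' model: fixed year mean plus the individual's genetic value plus permanent
#' environment, population, plot, year-by-progeny and residual draws, each
#' Gaussian with its configured variance.
#'
#' When `cfg$h2` is set, the nuisance variances are solved so that the
#' generative heritability — total genetic variance over phenotypic variance,
#' plot variance excluded from the denominator as in the analysis formula —
#' equals the target: the non-genetic variance is split 15% year-by-progeny /
#' 85% residual, with plot variance set to 10% of it. Note that the
#' progeny-level mixed model estimates only the between-family part of the
#' genetic variance as \eqn{\sigma_g^2} (the within-family part loads on the
#' permanent-environment term), so REML estimates of \eqn{h^2} on this
#' generator sit below the generative target; the attached `truth`
#' attributes report both decompositions.
#'
#' @param g a [genotype_matrix()] with family labels.
#' @param arch a `genetic_architecture` from [simulate_architecture()].
#' @param cfg a [sim_config()].
#' @param seed optional seed overriding the trial child stream.
#' @return a list with `records` (a [pheno_records()] data.frame) and
#'   `truth` (data.frame of true genetic and breeding values, with the
#'   simulated variance components attached as attribute `"components"`).
#' @export
simulate_trials <- function(g, arch, cfg, seed = NULL) {
  set.seed(if (is.null(seed)) .child_seeds(cfg$seed)[3] else seed)
  G <- arch$values$total
  n <- length(G)
  fam <- g$family
  if (is.null(fam)) stop("genotype matrix must carry family labels")
  pop <- if (is.null(g$population)) rep("P1", n) else g$population
  fam_means <- tapply(G, fam, mean)
  B <- stats::var(as.numeric(fam_means))
  W <- mean(tapply(G, fam, stats::var))
  sigma_G <- stats::var(G)
  if (!is.null(cfg$h2)) {
    h2 <- cfg$h2
    stopifnot(h2 > 0, h2 < 1)
    rem <- sigma_G * (1 - h2) / h2
    vc <- list(sigma_p2 = 0, sigma_r2 = 0, sigma_b2 = 0.10 * rem,
               sigma_i2 = 0.15 * rem, sigma_e2 = 0.85 * rem)
  } else vc <- cfg$vc
  if (any(unlist(vc) < 0)) stop("negative variance component")

  years <- sprintf("Y%d", seq_len(cfg$n_years))
  year_mean <- cfg$mu + stats::rnorm(cfg$n_years, 0, cfg$year_sd)
  plot_of <- sample(rep(seq_len(cfg$n_plots), length.out = n))
  plot_eff <- stats::rnorm(cfg$n_plots, 0, sqrt(vc$sigma_b2))
  perm_eff <- stats::rnorm(n, 0, sqrt(vc$sigma_p2))
  pops <- unique(pop)
  pop_eff <- stats::setNames(stats::rnorm(length(pops), 0,
                                          sqrt(vc$sigma_r2)), pops)
  fams <- unique(fam)
  int_eff <- matrix(stats::rnorm(length(fams) * cfg$n_years, 0,
                                 sqrt(vc$sigma_i2)),
                    length(fams), cfg$n_years, dimnames = list(fams, years))
  rec <- do.call(rbind, lapply(seq_len(cfg$n_years), function(yi) {
    data.frame(id = rownames(g$dosage), progeny = fam, population = pop,
               year = years[yi], plot = sprintf("plot%02d", plot_of),
               trait = cfg$trait,
               value = year_mean[yi] + G + perm_eff + pop_eff[pop] +
                 plot_eff[plot_of] + int_eff[cbind(fam, years[yi])] +
                 stats::rnorm(n, 0, sqrt(vc$sigma_e2)),
               stringsAsFactors = FALSE)
  }))
  rownames(rec) <- NULL
  truth <- data.frame(id = rownames(g$dosage),
                      genetic_value = G,
                      breeding_value = arch$values$additive,
                      stringsAsFactors = FALSE)
  comp <- c(sigma_g2 = sigma_G, sigma_p2 = vc$sigma_p2,
            sigma_r2 = vc$sigma_r2, sigma_b2 = vc$sigma_b2,
            sigma_i2 = vc$sigma_i2, sigma_e2 = vc$sigma_e2)
  attr(truth, "components") <- comp
  attr(truth, "h2") <- as.numeric(
    comp["sigma_g2"] / sum(comp[c("sigma_g2", "sigma_p2", "sigma_r2",
                                  "sigma_i2", "sigma_e2")]))
  # the progeny-model view of the same quantities: between-family genetic
  # variance is what the mixed model attributes to sigma_g2
  attr(truth, "family_components") <- c(between = B, within = W)
  attr(truth, "h2_progeny") <- as.numeric(
    B / (B + W + vc$sigma_p2 + vc$sigma_r2 + vc$sigma_i2 + vc$sigma_e2))
  list(records = pheno_records(rec), truth = truth)
}

#' Simulate genotypes, architecture and trials in one call
#'
#' Convenience wrapper running [simulate_population()],
#' [simulate_architecture()] and [simulate_trials()] with independent child
#' seed streams derived from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genotypes`, `architecture`, `records`, `truth`.
#' @export
simulate_dataset <- function(cfg) {
  seeds <- .child_seeds(cfg$seed)
  g <- simulate_population(cfg, seed = seeds[1])
  arch <- simulate_architecture(g, cfg, seed = seeds[2])
  tr <- simulate_trials(g, arch, cfg, seed = seeds[3])
  list(genotypes = g, architecture = arch, records = tr$records,
       truth = tr$truth)
}

#' Simulate records directly from the progeny-trial variance-component model
#'
#' Draws every term of the analysis mixed model from its Gaussian
#' distribution with user-specified variances: progeny effects, individual
#' permanent environment, population, plot, year-by-progeny interaction and
#' residual. Useful as an oracle for REML parameter recovery, where the true
#' components must be known exactly.
#'
#' @param n_progenies,fam_size,n_years design dimensions.
#' @param components named vector/list with `sigma_g2`, `sigma_p2`,
#'   `sigma_r2`, `sigma_b2`, `sigma_i2`, `sigma_e2`.
#' @param n_plots number of plots (0 to omit the plot term).
#' @param n_populations number of population groups progenies are split into.
#' @param mu overall mean; `year_sd` the spread of fixed year means.
#' @param year_sd standard deviation of fixed year means.
#' @param trait trait label.
#' @param seed RNG seed.
#' @return a [pheno_records()] data.frame; the drawn effects are attached as
#'   attribute `"effects"`.
#' @export
simulate_vc_records <- function(n_progenies = 13, fam_size = 15, n_years = 3,
                                components = c(sigma_g2 = 1, sigma_p2 = 0,
                                               sigma_r2 = 0, sigma_b2 = 0,
                                               sigma_i2 = 0, sigma_e2 = 1),
                                n_plots = 15, n_populations = 1,
                                mu = 10, year_sd = 1, trait = "trait",
                                seed = 1) {
  set.seed(seed)
  vc <- as.list(components)
  n <- n_progenies * fam_size
  fam <- rep(sprintf("F%02d", seq_len(n_progenies)), each = fam_size)
  ids <- sprintf("%s_%02d", fam, rep(seq_len(fam_size), n_progenies))
  pops <- sprintf("P%d", rep(seq_len(n_populations),
                             length.out = n_progenies))
  pop <- pops[match(fam, sprintf("F%02d", seq_len(n_progenies)))]
  years <- sprintf("Y%d", seq_len(n_years))
  year_mean <- mu + stats::rnorm(n_years, 0, year_sd)
  g_eff <- stats::setNames(stats::rnorm(n_progenies, 0, sqrt(vc$sigma_g2)),
                           unique(fam))
  p_eff <- stats::setNames(stats::rnorm(n, 0, sqrt(vc$sigma_p2)), ids)
  r_eff <- stats::setNames(stats::rnorm(n_populations, 0, sqrt(vc$sigma_r2)),
                           unique(pops))
  plot_of <- if (n_plots > 0) sample(rep(seq_len(n_plots), length.out = n))
             else rep(1L, n)
  b_eff <- stats::rnorm(max(plot_of), 0, sqrt(vc$sigma_b2))
  i_eff <- matrix(stats::rnorm(n_progenies * n_years, 0, sqrt(vc$sigma_i2)),
                  n_progenies, n_years,
                  dimnames = list(unique(fam), years))
  rec <- do.call(rbind, lapply(seq_len(n_years), function(yi) {
    data.frame(id = ids, progeny = fam, population = pop, year = years[yi],
               plot = sprintf("plot%02d", plot_of), trait = trait,
               value = year_mean[yi] + g_eff[fam] + p_eff[ids] + r_eff[pop] +
                 b_eff[plot_of] + i_eff[cbind(fam, years[yi])] +
                 stats::rnorm(n, 0, sqrt(vc$sigma_e2)),
               stringsAsFactors = FALSE)
  }))
  rownames(rec) <- NULL
  out <- pheno_records(rec)
  attr(out, "effects") <- list(g = g_eff, p = p_eff, r = r_eff, b = b_eff,
                               i = i_eff, year_mean = stats::setNames(year_mean, years))
  out
}
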