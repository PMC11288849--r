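---
title: "Stacked genomic prediction: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked genomic prediction: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selstack)
```

# The problem

Perennial-crop breeding programs phenotype families of candidate genotypes
over several years and want to rank candidates by additive genetic merit as
early as possible. Genomic selection replaces later phenotyping rounds with
predictions from dense SNP genotypes. `selstack` implements a stacked
generalization (stacking ensemble) approach to this prediction problem:
fourteen heterogeneous base learners produce genomic estimated breeding
values (GEBVs), and a second-level meta-learner combines their predictions
into the final GEBV. The package covers the whole workflow — phenotype
adjustment by a multi-year mixed model, marker quality control, the base
learners, four level-one metadata constructions, six meta-learners, a
repeated-holdout evaluation protocol, and a family-structured population
simulator that makes every stage testable without external data.

# Phenotype adjustment

Multi-year records from a progeny trial are modelled as

$$y = Xu + Zg + Wp + Vr + Tb + Ri + e$$

with fixed year means $u$ and independent Gaussian random effects: progeny
genetic effects $g \sim N(0, I\sigma_g^2)$, individual permanent-environment
effects $p \sim N(0, I\sigma_p^2)$, population effects
$r \sim N(0, I\sigma_r^2)$, plot effects $b \sim N(0, I\sigma_b^2)$,
year-by-progeny interactions $i \sim N(0, I\sigma_i^2)$ and residuals
$e \sim N(0, I\sigma_e^2)$. All covariances are identity matrices, which
makes the genetic term identifiable only at the progeny level; the
within-family genetic signal is absorbed by the permanent-environment term.
`fit_vc_reml()` estimates the six components by EM-REML on the mixed-model
equations (convergence when the largest relative component change drops
below `1e-8`, at most 500 iterations, components floored at `1e-10`). EM
was preferred over average-information updates for robustness at this data
scale (a few hundred records, a few hundred random levels); it is slower
near boundary optima but never overshoots, and the REML log-likelihood is
non-decreasing by construction — the fit stores the likelihood trace so
this can be asserted. Terms whose classification has fewer than two levels
are dropped, as are the permanent-environment term without repeated records
and the year-by-progeny term in single-year data (either would duplicate
another term's design).

Heritability is computed as
$h^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_p^2 + \sigma_r^2 + \sigma_i^2 +
\sigma_e^2)$. The plot component is deliberately excluded from the
denominator, matching the convention for this trial type; a flag restores
it. The adjusted phenotype fed to all learners is

$$y^*_i = \operatorname{mean}_j\,\bigl(y_{ij} - \hat u_{year} -
\hat b_{plot} - \hat i_{year\times progeny}\bigr),$$

i.e. only year, plot and year-by-progeny effects are removed, leaving
progeny, permanent-environment and population signal in $y^*$. An
alternative reading — using the genetic BLUP itself as $y^*$ — would shrink
family means toward zero and discard within-family contrasts entirely; we
follow the per-record correction and note the choice here because the two
conventions give visibly different downstream predictive abilities.

# Base learners

**GBLUP.** $y^* = Xb + Zu + e$ with $u \sim N(0, G\sigma_g^2)$ and the
VanRaden genomic relationship matrix $G = WW^\top / \sum_j 2p_j(1-p_j)$
over column-centered dosages ($W_{ij} = M_{ij} - 2p_j$ for dosages coded
0/1/2). We orient all dosages as counts of the alternate allele. Note the
$n \times n$ cross-product: an individual-by-individual kernel is what the
model requires. Variances are estimated by REML profiled over
$\sigma_g^2/\sigma_e^2$ on the spectral decomposition of $G$. Test
genotypes are always centered with training-set allele frequencies, so no
test information leaks into the kernel; whether pooled or training
frequencies should be used is genuinely open, and the leak-free option was
chosen. Predictions extend to unphenotyped individuals through
$\hat u_{test} = G_{test,train} G_{train,train}^{-1} \hat u_{train}$ with a
`1e-8` diagonal ridge.

**Regression trees, RF and QRF.** Trees split exhaustively over candidate
features and midpoints between consecutive distinct observed values,
minimizing the two-region residual sum of squares with regions
$R_1 = \{x_j < s\}$, $R_2 = \{x_j \ge s\}$; ties break to the lowest
feature index, then the smallest split value. The random forest grows 500
unpruned trees on bootstrap resamples with $\lceil v/3 \rceil$ candidate
features per node and leaf-size control `min_node = 5` (the reference
defaults for regression forests; the usual $m = v/3$ convention comes
without a rounding rule, so we take the ceiling). The quantile regression
forest shares the identical construction but keeps each leaf's training
observations: a query $x$ assigns each training observation the weight
$w_i(x) = \frac{1}{T}\sum_t \frac{\#\{i \in \text{leaf}_t(x)\}}
{|\text{leaf}_t(x)|}$, counting bootstrap multiplicities (the behavior of
the reference QRF implementation), and the $\tau$-quantile is the smallest
training response with $\hat F(y|x) = \sum_i w_i 1\{Y_i \le y\} \ge \tau$.
The nine quantile learners ($\tau = 0.1, \dots, 0.9$) read nine quantiles
off one shared fitted forest — the weights do not depend on $\tau$, so the
output is identical to nine separate fits under a shared seed policy and
nine times cheaper. The split search is implemented in C++ (as every
regression-forest package does), with a histogram fast path for
low-cardinality columns such as SNP dosages; forests are reproducible
bit-for-bit because bootstrap rows are drawn from R's RNG and per-tree
feature sampling uses seeds derived from it.

**MARS.** Multivariate adaptive regression splines build a basis of
products of hinge functions $(x_j - t)_+$, $(t - x_j)_+$ with knots at
observed feature values (for dosage data that means $t \in \{0, 1, 2\}$,
which caps how finely a single marker can be modelled — a documented
consequence, not a bug). The forward pass repeatedly adds the reflected
pair (parent term times new hinge pair) with the largest training-RSS
reduction, never multiplying two hinges on the same feature, up to
`max_terms = 21` terms (the cap is not stated by the convention we follow;
21 terms keeps up to ten hinge pairs and is configurable). The backward
pass deletes terms greedily by generalized cross-validation

$$GCV = \frac{RSS/N}{(1 - C(M)/N)^2}, \qquad C(M) = M + d\,(M-1)/2,$$

with per-knot cost $d = 3$, and returns the submodel with the global GCV
minimum along the deletion path. $M$ counts all terms including the
intercept, so $C(1) = 1$ for the intercept-only model. Degrees 1-3 give
the additive model and second/third-order interaction variants. Least
squares uses QR with collinear-column pruning at tolerance `1e-10`; the
forward pass stops when the best RSS improvement falls below `1e-10`.

# The stacking layer

Level-one metadata is built from **out-of-fold** base-learner predictions:
the training set is split into five inner folds, every learner predicts
each fold from the other four, and the per-learner inner predictive
ability (Pearson correlation of out-of-fold predictions with $y^*$) is
recorded. Training the meta-learner on in-sample predictions instead would
let strong learners leak their training fit into the combination weights;
the naive variant is available behind `naive = TRUE` for comparison, but
the out-of-fold protocol is the default and the one used everywhere in
this package. The learners are then refit on the full training set for
test-time prediction.

Four metadata variants are supported: all fourteen learner columns
(`GEBV-BL`); the same plus the centered SNP block (`GEBV-BL+SNP`); only
learners whose inner predictive ability strictly exceeds the mean over all
learners (`GEBV-BL-Best`, falling back to all learners with a warning when
none strictly exceeds); and the best subset plus SNPs. The strict
comparison implements "exceeding the average"; selection uses inner
abilities only, so test data never influences it.

Six meta-learners:

* **SSM** — the unweighted mean of the learner columns.
* **SWR** — "weighted regression", implemented as least squares constrained
  to non-negative coefficients normalized to sum to one, the classic
  stacked-regressions choice; the constraint is solved by a Lawson-Hanson
  active-set NNLS written here (no suitable solver is among the package's
  dependencies). The definition is deliberately swappable.
* **SR** — ordinary least squares with intercept on the metadata columns;
  collinear designs fall back to the minimum-norm pseudo-inverse solution
  with a warning.
* **SRR** — ridge regression on standardized metadata columns, intercept
  unpenalized, penalty chosen by inner 5-fold cross-validation over a
  50-point logarithmic grid on $[10^{-4}, 10^4]$.
* **SRF** — a random forest on the metadata columns (forest defaults).
* **S2KGBLUP** — a two-kernel GBLUP $y^* = Xb + u_1 + u_2 + e$ with
  $u_1 \sim N(0, K_1\sigma_1^2)$ on the VanRaden marker kernel and
  $u_2 \sim N(0, K_2\sigma_2^2)$ on a kernel of base-learner predictions;
  it requires a `+SNP` variant. No construction for the prediction kernel
  is prescribed anywhere, so we standardize the learner columns to mean 0
  and unit (population) variance and take $K_2 = PP^\top/q$ — the exact
  analogue of a genomic relationship matrix with predictions in place of
  markers. Its variances are estimated by EM-REML in the
  projection-matrix (V) form, which needs no kernel inverses and therefore
  handles the rank-deficient prediction kernel exactly; kernel diagonals
  still receive a `1e-8` ridge before the cross-kernel solves used at
  prediction time.

SSM and SWR combine *predictions*, so they always operate on the learner
columns only; SR, SRR and SRF consume the full metadata matrix including
the SNP block when present. This distinction is our reading of the variant
definitions: averaging raw SNP dosages into a GEBV would be meaningless.

# Evaluation protocol

`run_experiment()` repeats a 70/30 uniform holdout ten times
($\lfloor 0.7 n \rfloor$ training individuals; 136/59 at $n = 195$).
Predictive ability is the Pearson correlation between test GEBVs and
adjusted phenotypes; the standard error is the standard deviation over
replicates divided by $\sqrt{n_{reps}}$ (no formula is prescribed; this is
the conventional one). MSE is the plain mean squared difference. Pairwise
Spearman correlations and top-decile agreement (shared fraction of the top
$\lceil 0.1 n \rceil$, boundary ties broken by stable index order) are
computed on test predictions pooled over replicates, and the report states
this pooling. Gains are reported as the percentage ratio of a method's mean
predictive ability to GBLUP's.

# The simulator

`simulate_dataset()` emulates a small perennial progeny trial: six founders
in two pools of three, crossed into 13 full-sib families of 15 (195
individuals), genotyped for biallelic SNPs evenly spaced on 11 chromosomes.
Founder allele frequencies are uniform on [0.05, 0.5]; gametes recombine by
a Haldane (no-interference) map — the simplest defensible meiosis model.
The genetic architecture samples QTLs without replacement and draws
additive effects, dominance deviations and pairwise additive-by-additive
epistatic effects on products of mean-centered dosages; each component is
rescaled so the realized variance shares match the configuration exactly.
Pairwise products are sufficient to create the non-linear signal that
interaction-capable learners should exploit; higher-order epistasis is out
of scope. Phenotype records add fixed year means (drawn once per
simulation), permanent-environment, population, plot, year-by-progeny and
residual Gaussian noise.

When a target heritability is requested, it is defined at the individual
scale — total genetic variance over phenotypic variance, plot variance
excluded from the denominator exactly as in the analysis formula — and the
non-genetic variance is split 15% year-by-progeny / 85% residual with plot
variance at 10% of it. Because the analysis model sees genetics only at
the progeny level, REML estimates of $h^2$ on marker-simulated data sit
below this generative target (the between-family fraction of genetic
variance is roughly half for full sibs, and smaller still for epistatic
components); the simulator therefore also reports the progeny-scale
decomposition. REML *recovery* is checked against
`simulate_vc_records()`, which draws every term of the analysis model
directly with known components — there the target is exact by
construction. One master seed drives independent child streams for the
population, architecture, trial and split stages, so stages can be rerun
in isolation and the entire pipeline is bitwise reproducible.

What the simulator does **not** emulate: linkage disequilibrium beyond
family co-segregation, genotyping error, missing-data patterns of real
arrays, selection history, augmented-block field layouts (a generic random
plot grouping stands in for the real design, which is not described in
enough detail to copy), multi-trait correlations, and non-Gaussian trait
scales such as ordinal disease scores. Passing tests on this generator
demonstrate internal correctness and qualitative behavior, not performance
on real coffee data.

# Numerical choices

* Missing dosages are mean-imputed ($2\hat p_j$) because every learner
  needs a complete matrix; the policy is isolated in `impute_missing()`
  and replaceable. How missing genotypes were handled after quality
  control in the motivating study is not stated anywhere we could follow.
* Kinship solves add a `1e-8` diagonal ridge; positive semi-definiteness
  is checked with tolerance `1e-8` on the most negative eigenvalue.
* The SNP quality filter excludes markers with call rate below 90% or
  minor allele frequency below 5% — the sentence defining the rule is
  grammatically ambiguous, and keeping *only* rare markers would be
  useless for prediction, so the conventional exclusion is implemented.
* Split candidates at value midpoints, tie-breaks lowest-feature-first:
  the standard regression-tree choice where none is prescribed.
* EM-REML floors components at `1e-10`; zero-variance data therefore
  reports all components at the floor rather than failing.
* Ridge CV ties resolve to the smallest-index (largest-error-free) grid
  point via `which.min`.

# Problem sizes used by the tests

The shipped test suite and the acceptance script size their simulations to
run comfortably on a single CPU: the end-to-end stacking experiment uses
195 individuals, 500 markers, 100 QTLs with a 50% pairwise-epistasis
share, target $h^2 = 0.3$, all 14 base learners, all 4 variants and all 6
meta-learners over 10 holdout replicates; REML recovery uses the full
13x15x3 design over 20 seeds; quantile-forest calibration uses 500
training and 500 held-out observations with 200 trees. The determinism
check runs a reduced configuration (6 families of 10, 120 markers, 50
trees, 2 replicates) through the entire pipeline twice.

# Known limitations

* SEL does not reliably beat GBLUP on this package's polygenic synthetic
  conditions (100 QTLs): with many small effects, sparse learners (MARS)
  and leaf-based forests are individually much weaker than GBLUP, and the
  ensemble at best matches it. The advantage reported on real coffee
  traits plausibly depends on trait architectures (few large non-additive
  effects, non-Gaussian scales) that the generator's defaults do not
  create.
* EM-REML converges slowly when a variance sits near zero or two kernels
  are nearly collinear; fits return `converged = FALSE` with a warning
  rather than failing, and fixed-variance arguments are available.
* The progeny-level genetic term means marker-based within-family signal
  is never attributed to $\sigma_g^2$; this is a property of the printed
  model, not of the estimator.
* MARS knots at observed dosage values limit each marker to at most two
  effective breakpoints.
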