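---
title: "Uncertainty-aware imputation and classification with missgp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Uncertainty-aware imputation and classification with missgp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missgp)
```

## The problem

Clinical feature tables — for example per-patient summaries of vital signs
before ICU discharge — are rarely complete. Deleting incomplete patients
wastes most of the cohort; filling each hole with a single number (a column
mean, or the last observation carried forward) hides the fact that the
filled value is a guess. `missgp` implements a two-stage alternative:

1. **Imputation with uncertainty.** A Bayesian Gaussian process latent
   variable model (GPLVM) is trained on the complete rows. Each missing
   cell of an incomplete row is then imputed as a full Gaussian
   distribution: a mean $\pi_{ij}$ and a standard deviation $\sigma_{ij}$.
2. **Classification that uses the uncertainty.** A constrained support
   vector machine (cSVM) propagates the per-cell distributions into the
   classifier instead of discarding them: it samples $p$ complete versions
   of the training data, trains a vanilla SVM on each, and then solves a
   modified dual program whose linear term couples the final classifier to
   that ensemble.

## The imputation model

Write the complete training table as $Y \in \mathbb{R}^{N \times M}$
(columns standardized to zero mean, unit sd; the statistics are stored and
re-applied at prediction time). Each column is modelled as a noisy GP over
shared latent inputs $X \in \mathbb{R}^{N\times Q}$:

$$ y_{nd} = f_d(x_n) + \varepsilon_{nd}, \qquad
   f_d \sim \mathcal{GP}(0, k), \qquad
   \varepsilon_{nd} \sim N(0, \tau^2), $$

with the squared-exponential ARD kernel
$k(x, x') = \sigma_f^2 \exp\{-\tfrac12\sum_q (x_q - x'_q)^2/\ell_q^2\}$
and a standard-normal prior on the rows of $X$. The mean function is fixed
to zero — the data are standardized first, so a free mean would be
redundant.

Because the latents enter the kernel nonlinearly, the marginal likelihood
is intractable; the package maximizes the sparse variational lower bound
built from $m$ inducing inputs and a factorized Gaussian posterior
$q(X) = \prod_n N(x_n; \mu_n, \mathrm{diag}(s_n^2))$. The bound needs only
the closed-form kernel expectations ("psi statistics")
$\psi_0 = \sum_n E_q[k(x_n,x_n)]$, $\Psi_1[n,i] = E_q[k(x_n, z_i)]$ and
$\Psi_2[i,j] = \sum_n E_q[k(x_n,z_i)k(x_n,z_j)]$, all available analytically
for this kernel. `elbo()` exposes the bound and its two parts (expected
log-likelihood term and KL term); the KL term is exactly zero when $q$
equals the prior, and on tiny instances the bound is verified in the test
suite against the exact evidence computed by tensor-product Gauss–Hermite
quadrature over the latents.

Everything — kernel hyperparameters, noise variance, inducing inputs and
the variational posterior — is optimized jointly by L-BFGS-B with
hand-derived analytic gradients (checked against finite differences in the
tests). Optimization restarts from perturbed initializations
(`n_restarts`, default 2) and keeps the best bound.

### Imputing a new row

For a partially observed row $z^* = [z^*_O, z^*_U]$, a Gaussian
$q(x^*)$ is optimized against the bound restricted to the observed
dimensions, with the training posterior held fixed. Optimization starts
both from the prior and from the training row nearest in observed-subspace
Euclidean distance, keeping the better bound. (Refreshing the *training*
latents at test time would be the fully Bayesian treatment; holding them
fixed is a deliberate simplification that keeps prediction cost per row
independent of $N$.)

The missing dimensions are then imputed by the exact first and second
moments of the latent function values under $q(x^*)$ — again closed-form
psi statistics, no sampling — and the observation noise is added:

$$ \pi_{d} = E[h^*_d], \qquad
   \sigma_d^2 = \mathrm{Var}[h^*_d] + \tau^2 \ \ge\ \tau^2 . $$

The noise floor $\sigma^2 \ge \tau^2$ holds for every imputed cell. A row
with no observed entries falls back to the latent prior (mean 0, variance
$\sigma_f^2 + \tau^2$) with a warning.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `latent_dim` (Q) | 5 | latent dimensions; ARD lengthscales prune unused ones, so a generous value is safe as long as $Q < M$ |
| `n_inducing` (m) | `min(50, N/2)` | inducing inputs of the sparse bound; more is slower and more accurate |
| `maxit` | 200 | L-BFGS-B iterations per restart |
| `n_restarts` | 2 | perturbed re-initializations, best bound wins |
| `init_noise_var` | 0.1 | starting $\tau^2$ in standardized units |
| `jitter` | `1e-6` | diagonal inflation of kernel matrices, escalated ×10 up to `1e-3` on factorization failure |

The default `latent_dim = 5` is chosen small relative to the 15–30
correlated features the package targets; the ARD test in the suite shows
the fitted lengthscales of surplus dimensions grow away when the true
latent dimension is smaller.

## The constrained SVM

Given labels $y_j \in \{-1,+1\}$ and the soft-margin SVM dual with RBF
kernel $K(s,s') = \exp(-\|s-s'\|^2/2\sigma^2)$, the uncertainty-aware
classifier is built in three steps:

1. draw $p$ completions of the data, each missing cell independently from
   $N(\pi_{ij}, \sigma_{ij}^2)$ (observed cells shared by all draws);
2. train one vanilla SVM per completion, giving weight vectors
   $w_i = \sum_k \alpha_{ik} y_{ik} \phi(s_{ik})$;
3. on one further fresh completion solve the penalized dual
$$ \max_\alpha \sum_j \alpha_j
   - \tfrac12 \sum_{j,k} \alpha_j\alpha_k y_jy_k K(s_j,s_k)
   + \lambda \sum_j \alpha_j y_j W(s_j), \quad
   0 \le \alpha_j \le C,\ \textstyle\sum_j \alpha_j y_j = 0, $$
   where $W(s) = \sum_i w_i^\top \phi(s)$ is evaluated through the ensemble
   members' kernel expansions.

This dual is the KKT dual of the primal
$\min \tfrac12 w^\top w + \lambda \sum_i w^\top w_i + C\sum_j \xi_j$, a
penalty on similarity with the pre-trained weight vectors, whose
stationarity condition gives $w = \sum_j \alpha_j y_j \phi(s_j) - \lambda
\sum_i w_i$. With $\lambda = 0$ the solution coincides exactly with the
vanilla SVM, a reduction the test suite asserts to $10^{-5}$.

**Decision rule.** The penalized program pins down $\alpha$, but not how to
score new points, and two readings coexist. The stationarity condition
suggests $f(s) = \sum_j \alpha_j y_j K(s_j,s) - \lambda W(s) + b$
("full"); alternatively one scores with the penalized solution's own
kernel expansion, $f(s) = \sum_j \alpha_j y_j K(s_j,s) + b$
("expansion-only"), letting the penalty act purely through which support
vectors are selected and how they are weighted. The full rule degrades as
$p$ grows — the subtracted $\lambda\sum_i w_i$ term eventually dominates
the classifier and anti-correlates it with the labels — whereas the
expansion-only rule is the one that actually improves on the vanilla SVM
under imputation uncertainty, which is the method's purpose. The package
therefore scores with `decision_rule = "expansion-only"` by default and
keeps `"full"` available for ablation; each rule carries its matching
intercept (KKT bias for the full rule, a free-support-vector recalibration
for the default).

**Solver.** Both duals are solved by sequential minimal optimization with
second-order working-set selection, written for this package because the
penalized dual needs a general linear term. Default KKT tolerance is
$10^{-8}$ with an iteration cap warning; the end-to-end pipeline uses
$10^{-3}$ (the common libsvm default) because its box constraint
$C = 10^4$ makes the strict tolerance needlessly expensive. Solutions are
cross-checked in the tests against `kernlab::ipop`, an independent
interior-point solver, and (for the rare instance whose interior-point
factorization goes singular) against a scipy SLSQP solve.

**Defaults.** $p = 200$, $\lambda = 1$, $C = 10^4$; the kernel scale
$\sigma$ is chosen by 5-fold cross-validated AUC of the vanilla SVM over a
grid around the median pairwise distance, ties going to the smaller scale.
Accuracy is insensitive to $p$ beyond a few dozen; $p$ mainly controls the
smoothness of the penalty term.

## Reference imputers and metrics

`mean_impute()` (training-column means) and `locf_impute()` (last
observation carried forward along a user-supplied row order, column-mean
fallback for leading holes) serve as baselines; both return zero
imputation sd. LOCF on a cross-sectional table is not well defined — the
row ordering is an interpretation, and the package makes it an explicit
argument.

Imputation is scored by the mean absolute error over missing cells on the
standardized scale,
$\mathrm{MAE} = \frac{1}{N_{miss}}\sum_{(i,j)\in M} |\pi_{ij} - y_{ij}|$,
and by the coverage of the $\pi_{ij} \pm 2\sigma_{ij}$ bounds (nominally
the two-sigma Gaussian mass, ≈ 0.954; boundary cells count as covered).
Classification is scored by the rank-based ROC/AUC (trapezoid, half credit
for ties — the Mann–Whitney convention), TPR interpolated linearly at fixed
FPR levels, operating points at fixed sensitivity or specificity 0.85, and
stratified case-resampling percentile bootstrap intervals (default 1000
replicates).

## The synthetic cohort generator

Real EHR cohorts of this kind are credential-gated, so the package ships a
generator that emulates their structure: `n_instances` rows of
`n_features` correlated continuous features driven by a low-dimensional
standard-normal latent state through either a random linear mixing or a GP
draw, plus Gaussian noise (`noise_var`, default 0.1 relative to unit
signal scale), columns standardized. Binary labels follow a logistic model
on the latent state whose intercept is solved to hit a target positive
rate (default 11.8%, a typical 30-day heart-failure readmission rate).
Default size is 1000 × 15, a scale at which the full pipeline runs in
seconds to minutes on one core.

Missingness is induced by a regression-quartile, missing-at-random
mechanism: for each feature a linear regression on the remaining features
is fitted on the complete data and its fitted values' quantiles computed;
a fraction of instances (20% or 30%) is selected at random; within a
selected instance a feature is masked iff its fitted value falls in the
configured quantile window (default between the median and the 75th
percentile, so about a quarter of the features of a selected instance go
missing). Because the rule involves a cell only through its fitted value —
a function of the *other* features — the mechanism is MAR. A variant that
thresholds the observed value instead (`mar_rule = "observed"`) is
available; it makes missingness depend on the value itself (MNAR-like) and
is not the default.

What the generator does **not** emulate: categorical/dummy demographics,
raw vital-sign time series (features stand for their window summaries),
within-patient repeated stays, and real measurement error structure.
Passing tests on this generator shows the algorithms are implemented
correctly and behave as designed under latent low-rank structure with MAR
missingness; it does not by itself certify performance on any particular
clinical cohort.

## The experiment pipeline

`run_experiment()` ties the stages together under one seed: repeated
stratified 80/20 train/test splits (fold count unspecified in the protocol
it follows, so the package uses repeated splits, default 5); column
standardization with statistics from observed training cells only; GPLVM
trained on the complete training rows (capped at `max_train = 300` rows —
the embedding is learned from a small complete subset, and the cap keeps
the fit fast without hurting imputation accuracy at the default scale);
imputation of both splits with training-derived information only; optional
lasso feature selection (`glmnet`) on the training imputation means;
down-sampling of the majority class to 1:1; vanilla SVM on the imputation
means; cSVM on sampled completions; ROC/AUC on the held-out split. Every
stage seed derives deterministically from the global seed, so a rerun
reproduces the report bit for bit.

## Numerical choices and degenerate inputs

* Kernel matrices receive a `1e-6` diagonal jitter before factorization,
  escalated tenfold up to `1e-3` with an informative error beyond that.
* On near-linear data the ARD-RBF fit drifts to large lengthscales and
  signal variance (the regime where the RBF kernel mimics a linear one);
  the inducing Gram matrix is then ill-conditioned and the *value* of the
  bound becomes sensitive at the last few digits, though predictions stay
  stable. The model stores its squared lengthscales exactly as optimized
  so that re-evaluating the bound reproduces the stored value.
* The optimizer treats non-finite objective excursions as hard walls
  (value `1e10`, zero gradient) rather than failing.
* Ties in the kernel-scale grid search go to the smaller scale; ROC ties
  follow the Mann–Whitney half-credit convention; quantiles use R's type-7
  default.
* Degenerate rows (all features missing) are imputed from the latent prior
  with a warning; constant columns are an error naming the column.

## Known limitations

* Only continuous features are imputed; categorical columns are out of
  scope.
* The GPLVM trains on complete rows only — if no (or very few) complete
  rows exist, the embedding cannot be learned from this package alone.
* Per-row imputation stores per-cell standard deviations (the diagonal of
  the row's predictive covariance); completions are sampled cell-wise, so
  within-row posterior correlation between two *missing* cells is not
  propagated into the cSVM ensemble.
* The cSVM is binary-only and its scores are not calibrated probabilities.

## A small worked run

```{r example, eval = FALSE}
b <- make_benchmark(sim_config(n_instances = 400, n_features = 10,
                               latent_dim = 3, missing_fraction = 0.2,
                               seed = 1))
fit <- gplvm(b$data, latent_dim = 4, seed = 1)
imp <- predict(fit, b$data)
imputation_mae(imp, b$truth)        # GPLVM error, standardized units
imputation_mae(mean_impute(b$data), b$truth)
imputation_coverage(imp, b$truth)   # ~0.95 when calibrated

cf <- constrained_svm(imp, b$labels, p = 50, lambda = 1, C = 100,
                      seed = 1, tol = 1e-4)
evaluate_classifier(predict(cf, imp$values), b$labels, seed = 1)
```
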