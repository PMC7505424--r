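# missgp

Gaussian-process imputation of missing clinical features **with
uncertainty**, and a constrained SVM that carries that uncertainty into
classification.

## What problem this solves

Tabular clinical data — e.g. per-patient summaries of vital signs used to
predict 30-day readmission after an ICU stay — are full of holes: a
feature is missing whenever the underlying signal was not charted.
Single-value imputation (column mean, last observation carried forward)
throws away the information that the filled value is uncertain, and
classifiers trained on such tables inherit that hidden error.

`missgp` implements a two-stage framework for analysts building risk
models on incomplete feature tables:

1. **GPLVM imputation.** A Bayesian Gaussian process latent variable model
   is fitted to the complete rows by sparse variational inference: each
   standardized feature column is a noisy GP over a shared low-dimensional
   latent state with a squared-exponential ARD kernel,
   *y*<sub>nd</sub> = *f*<sub>d</sub>(*x*<sub>n</sub>) + ε,
   ε ~ N(0, τ²). Every missing cell (i, j) of an incomplete row is imputed
   as a Gaussian: mean π<sub>ij</sub> and standard deviation σ<sub>ij</sub>
   (predictive moments computed in closed form, noise included, so
   σ²<sub>ij</sub> ≥ τ²).

2. **Constrained SVM (cSVM).** *p* complete datasets are sampled from the
   imputation distributions; a vanilla kernel SVM **w**<sub>i</sub> is
   trained on each; the final classifier solves the dual QP

   max<sub>α</sub> Σα<sub>j</sub> − ½ ΣΣ α<sub>j</sub>α<sub>k</sub>y<sub>j</sub>y<sub>k</sub>K(s<sub>j</sub>,s<sub>k</sub>) + λ Σ α<sub>j</sub>y<sub>j</sub>W(s<sub>j</sub>),  0 ≤ α<sub>j</sub> ≤ C, Σα<sub>j</sub>y<sub>j</sub> = 0,

   where W(s) = Σ<sub>i</sub> **w**<sub>i</sub>ᵀφ(s) couples the solution
   to the ensemble. With λ = 0 this is exactly the vanilla SVM. The dual is
   solved by the package's own SMO solver (needed for the general linear
   term) and is verified against an independent interior-point solver in
   the tests.

The package also ships the reference imputers (mean, LOCF), the evaluation
metrics (standardized MAE over missing cells, ±2σ coverage, rank-based
ROC/AUC with stratified bootstrap CIs, operating points at fixed
sensitivity/specificity), a synthetic cohort generator with a
regression-quartile missing-at-random mechanism, and a one-seed experiment
pipeline. See the methods vignette (`vignettes/methods.Rmd`) for the model,
its assumptions and the design decisions.

## Worked example

```r
library(missgp)

## a synthetic cohort: 500 patients x 10 correlated features, binary
## outcome, 20% of patients with quartile-window MAR missingness
b <- make_benchmark(sim_config(n_instances = 500, n_features = 10,
                               latent_dim = 3, missing_fraction = 0.2,
                               seed = 1))
tr <- 1:400; te <- 401:500
train <- masked_matrix(b$data$values[tr, ])
test  <- masked_matrix(b$data$values[te, ])

fit <- gplvm(train, latent_dim = 4, seed = 1)
#> Bayesian GPLVM (sparse variational fit)
#>   training rows: 336   features: 10   latent dims: 4   inducing points: 50
#>   ELBO: -2965.797   noise sd: 0.3298   signal sd: 11.1495

imp <- predict(fit, train)
#> imputed_data (gplvm): 400 x 10, 176 imputed cells, median imputation sd 0.410
imputation_mae(imp, b$truth[tr, ])                       # 0.305
imputation_mae(mean_impute(train), b$truth[tr, ])        # 0.416
imputation_coverage(imp, b$truth[tr, ])                  # 0.972

cf <- constrained_svm(imp, b$labels[tr], p = 50, lambda = 1, C = 100,
                      seed = 1, tol = 1e-4)
evaluate_classifier(predict(cf, predict(fit, test)$values),
                    b$labels[te], seed = 1)
#> classifier evaluation: n = 100 (15 positives)
#>   AUC = 0.882 (95% CI 0.771, 0.966)
#>   at sensitivity 0.85: specificity = 0.776 (CI 0.597, 0.953)
#>   at specificity 0.85: sensitivity = 0.783 (CI 0.533, 1.000)
```

Reading the numbers: the GPLVM's mean absolute error on the held-back
cells (0.305, standardized units) is well below mean imputation's (0.416),
and 97.2% of the true values fall inside the π ± 2σ bounds — close to the
nominal two-sigma mass of 95.4%, i.e. the uncertainty estimates are
calibrated, slightly conservative. The cSVM trained on the imputation
distributions reaches a held-out AUC of 0.88 on this synthetic cohort.

A thin command-line interface over the same functions is installed at
`inst/cli/missgp.R` (subcommands `simulate`, `impute-fit`, `impute-apply`,
`baseline`, `csvm-train`, `csvm-predict`, `evaluate`, `pipeline`).

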