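#' Standardize train/test feature tables with training statistics
#'
#' Column means and standard deviations are computed over the observed
#' cells of the training data only and applied to both splits, so no test
#' information leaks into the scaling.
#'
#' @param train,test [masked_matrix()] objects (test may be `NULL`).
#' @return List with `train`, `test` (standardized masked matrices) and
#'   `stats` (per-column `mean`, `sd`, `columns`).
#' @export
standardize_split <- function(train, test = NULL) {
  stopifnot(inherits(train, "masked_matrix"))
  mu <- colMeans(train$values, na.rm = TRUE)
  sdv <- apply(train$values, 2, stats::sd, na.rm = TRUE)
  bad <- !is.finite(sdv) | sdv == 0
  if (any(bad))
    stop("constant or empty column(s) in training data: ",
         paste(train$column_names[bad], collapse = ", "), call. = FALSE)
  stats <- list(mean = mu, sd = sdv, columns = train$column_names)
  std <- function(mm) {
    v <- sweep(sweep(mm$values, 2, mu, "-"), 2, sdv, "/")
    masked_matrix(v, mm$mask)
  }
  list(train = std(train), test = if (!is.null(test)) std(test), stats = stats)
}

#' Invert a standardization
#'
#' @param values Standardized numeric matrix.
#' @param stats Statistics list from [standardize_split()].
#' @return Matrix on the original scale.
#' @export
unstandardize <- function(values, stats) {
  sweep(sweep(values, 2, stats$sd, "*"), 2, stats$mean, "+")
}

#' L1-penalized logistic feature selection
#'
#' Fits a lasso-regularized logistic regression (via \pkg{glmnet}) and
#' returns the indices of features with nonzero coefficients.  With
#' `penalty = NULL` the penalty is chosen by cross-validation
#' (`lambda.1se`).
#'
#' @param x Complete numeric matrix (e.g. imputation means).
#' @param y Binary labels.
#' @param penalty Lasso penalty `lambda`; `NULL` for cross-validation.
#' @param seed Seed for the cross-validation folds.
#' @return Integer vector of selected column indices (empty, with a
#'   warning, if all coefficients are zero).
#' @export
select_features <- function(x, y, penalty = NULL, seed = 1) {
  x <- as.matrix(x)
  y01 <- (svm_labels(y) + 1) / 2
  if (is.null(penalty)) {
    cv <- with_seed(derive_seed(seed, "lasso-cv"),
                    glmnet::cv.glmnet(x, y01, family = "binomial",
                                      alpha = 1, nfolds = 5))
    penalty <- cv$lambda.1se
  }
  fit <- glmnet::glmnet(x, y01, family = "binomial", alpha = 1,
                        lambda = penalty)
  co <- as.vector(stats::coef(fit))[-1]   # drop intercept
  idx <- which(abs(co) > 0)
  if (!length(idx)) warning("lasso selected no features at penalty ", penalty)
  idx
}

#' Down-sample the majority class
#'
#' Keeps the minority class whole and randomly subsamples the majority
#' class without replacement so the class ratio becomes `ratio`
#' (majority:minority; default 1, i.e. balanced).
#'
#' @param y Labels (coerced to -1/+1).
#' @param ratio Target majority:minority ratio (default 1).
#' @param seed Integer seed.
#' @return Sorted integer vector of retained row indices.
#' @export
downsample_majority <- function(y, ratio = 1, seed = 1) {
  y <- svm_labels(y)
  n_pos <- sum(y > 0); n_neg <- sum(y < 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes required", call. = FALSE)
  minority <- if (n_pos <= n_neg) 1 else -1
  n_min <- min(n_pos, n_neg); n_maj <- max(n_pos, n_neg)
  target <- floor(ratio * n_min)
  if (target >= n_maj) {
    warning("majority class already at or below the target ratio; no-op")
    return(seq_along(y))
  }
  maj_idx <- which(y != minority)
  keep <- with_seed(derive_seed(seed, "downsample"),
                    sample(maj_idx, target))
  sort(c(which(y == minority), keep))
}

#' Configuration for a full imputation-classification experiment
#'
#' @param benchmark A [sim_config()] describing the synthetic cohort, or a
#'   ready [make_benchmark()] bundle, or a list `(data, labels, truth)` with
#'   user data.
#' @param n_repeats Number of repeated stratified 80/20 splits (default 5).
#' @param split Training fraction (default 0.8).
#' @param imputers Character subset of `c("mean", "locf", "gplvm")`.
#' @param feature_selection Run lasso feature selection on the training
#'   imputation means (default `FALSE`; the synthetic features are all
#'   informative by construction).
#' @param downsample_ratio Majority:minority ratio after down-sampling
#'   (default 1, the balanced design).
#' @param gplvm Options list for [gplvm()]: `latent_dim`, `n_inducing`,
#'   `maxit`, `n_restarts`, `max_train` (cap on complete training rows used
#'   to learn the embedding, default 300).
#' @param csvm Options list: `p`, `lambda`, `C`, `kernel_scale` (`NULL`
#'   tunes it by cross-validated AUC on the vanilla SVM), `tol`,
#'   `train_on` (`"completion"`, the default, trains the final constrained
#'   stage on a fresh sampled completion; `"mean"` trains it on the
#'   imputation means, an ablation that makes the `lambda = 0` case
#'   coincide with the vanilla SVM row).
#' @param seed Global seed; all stage seeds derive from it.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(benchmark = sim_config(), n_repeats = 5,
                            split = 0.8,
                            imputers = c("mean", "locf", "gplvm"),
                            feature_selection = FALSE,
                            downsample_ratio = 1,
                            gplvm = list(), csvm = list(), seed = 1) {
  stopifnot(split > 0, split < 1, n_repeats >= 1)
  imputers <- match.arg(imputers, several.ok = TRUE)
  gdef <- list(latent_dim = 5, n_inducing = NULL, maxit = 150,
               n_restarts = 2, max_train = 300)
  cdef <- list(p = 200, lambda = 1, C = 10000, kernel_scale = NULL,
               tol = 1e-3, max_iter = 100000L, train_on = "completion")
  gdef[names(gplvm)] <- gplvm
  cdef[names(csvm)] <- csvm
  structure(list(benchmark = benchmark, n_repeats = n_repeats, split = split,
                 imputers = imputers, feature_selection = feature_selection,
                 downsample_ratio = downsample_ratio,
                 gplvm = gdef, csvm = cdef, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full imputation-classification experiment
#'
#' Reproduces the experimental protocol end to end on synthetic (or
#' supplied) data: repeated stratified train/test splits, standardization
#' with training statistics, imputation by each configured method, class
#' down-sampling of the training split, vanilla SVM on the imputation
#' means, constrained SVM on the GPLVM imputation distributions, and
#' ROC/AUC evaluation on the held-out split.  Fully deterministic given the
#' config seed.
#'
#' @param config A [pipeline_config()].
#' @param verbose Log stage progress to stderr (default `FALSE`).
#' @return Object of class `experiment_report`: `results` (one row per
#'   repeat x imputer x classifier with AUC and operating points),
#'   `summary` (means over repeats), `config`.
#' @export
run_experiment <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ...)

  bench <- config$benchmark
  if (inherits(bench, "sim_config")) bench <- make_benchmark(bench)
  data <- bench$data; labels <- bench$labels
  stopifnot(inherits(data, "masked_matrix"),
            length(labels) == nrow(data$values))
  y <- svm_labels(labels)
  N <- length(y)
  res <- list()

  for (rep_i in seq_len(config$n_repeats)) {
    split_seed <- derive_seed(config$seed, paste0("split-", rep_i))
    test_idx <- with_seed(split_seed, {
      n_te <- round((1 - config$split) * N)
      pos <- which(y > 0); neg <- which(y < 0)
      sort(c(sample(pos, round(length(pos) / N * n_te)),
             sample(neg, n_te - round(length(pos) / N * n_te))))
    })
    tr <- setdiff(seq_len(N), test_idx)
    say("repeat ", rep_i, ": ", length(tr), " train / ", length(test_idx),
        " test rows")
    std <- standardize_split(mm_rows(data, tr), mm_rows(data, test_idx))
    y_tr <- y[tr]; y_te <- y[test_idx]

    ## imputations (train and test imputed with train-derived information)
    imps <- list()
    for (im in config$imputers) {
      imps[[im]] <- switch(im,
        mean = list(
          train = mean_impute(std$train),
          test = mean_impute(std$test,
                             train_stats = list(mean = colMeans(std$train$values, na.rm = TRUE)))),
        locf = list(
          train = locf_impute(std$train),
          test = locf_impute(std$test,
                             train_stats = list(mean = colMeans(std$train$values, na.rm = TRUE)))),
        gplvm = {
          g <- config$gplvm
          comp <- which(complete_rows(std$train))
          if (length(comp) > g$max_train)
            comp <- with_seed(derive_seed(config$seed, paste0("gcap-", rep_i)),
                              sort(sample(comp, g$max_train)))
          say("  fitting GPLVM on ", length(comp), " complete rows")
          fit <- gplvm(std$train$values[comp, , drop = FALSE],
                       latent_dim = g$latent_dim, n_inducing = g$n_inducing,
                       standardize = FALSE, maxit = g$maxit,
                       n_restarts = g$n_restarts,
                       seed = derive_seed(config$seed, paste0("gplvm-", rep_i)))
          list(train = predict(fit, std$train), test = predict(fit, std$test),
               model = fit)
        })
    }

    ## optional feature selection on the first imputer's training means
    feat <- seq_len(ncol(data$values))
    if (isTRUE(config$feature_selection)) {
      feat <- select_features(imps[[1]]$train$values, y_tr,
                              seed = derive_seed(config$seed, paste0("fs-", rep_i)))
      if (!length(feat)) feat <- seq_len(ncol(data$values))
      say("  selected ", length(feat), " features")
    }
    sub_cols <- function(imp) imputed_data(
      imp$values[, feat, drop = FALSE], imp$sd[, feat, drop = FALSE],
      imp$mask[, feat, drop = FALSE], imp$train_stats, imp$method)

    ## class balancing of the training split
    keep <- downsample_majority(y_tr, ratio = config$downsample_ratio,
                                seed = derive_seed(config$seed, paste0("ds-", rep_i)))
    cs <- config$csvm

    for (im in names(imps)) {
      imp_tr <- sub_cols(imps[[im]]$train)
      imp_te <- sub_cols(imps[[im]]$test)
      x_tr <- imp_tr$values[keep, , drop = FALSE]
      x_te <- imp_te$values
      ks <- cs$kernel_scale
      if (is.null(ks))
        ks <- tune_kernel_scale(x_tr, y_tr[keep], C = cs$C,
                                seed = derive_seed(config$seed, paste0("ks-", rep_i)),
                                tol = cs$tol, max_iter = cs$max_iter)
      say("  [", im, "] kernel scale ", signif(ks, 4))
      svm_fit <- kernel_svm(x_tr, y_tr[keep], C = cs$C, kernel_scale = ks,
                            tol = cs$tol, max_iter = cs$max_iter)
      sc_svm <- stats::predict(svm_fit, x_te)
      res[[length(res) + 1L]] <- score_row(rep_i, im, "svm", sc_svm, y_te)

      {
        comps <- sample_completions(imp_tr, cs$p + 1L,
          seed = derive_seed(config$seed, paste0("csvm-", rep_i, im)))
        comps <- lapply(comps, function(m) m[keep, , drop = FALSE])
        ens <- if (all(imp_tr$sd[keep, ] == 0)) {
          ## deterministic imputation: all completions coincide, so the
          ## ensemble is p copies of one fit
          rep(list(kernel_svm(comps[[1]], y_tr[keep], C = cs$C,
                              kernel_scale = ks, tol = cs$tol,
                              max_iter = cs$max_iter)), cs$p)
        } else {
          train_ensemble(comps[seq_len(cs$p)], y_tr[keep], C = cs$C,
                         kernel_scale = ks, tol = cs$tol,
                         max_iter = cs$max_iter)
        }
        S_new <- if (identical(cs$train_on, "mean")) x_tr else
          comps[[cs$p + 1L]]
        cfit <- solve_csvm_dual(S_new, y_tr[keep], ens, lambda = cs$lambda,
                                C = cs$C, kernel_scale = ks, tol = cs$tol,
                                max_iter = cs$max_iter)
        sc_csvm <- stats::predict(cfit, x_te)
        res[[length(res) + 1L]] <- score_row(rep_i, im, "csvm", sc_csvm, y_te)
      }
    }
  }
  results <- do.call(rbind, res)
  summary <- stats::aggregate(cbind(auc, spec_at_sens, sens_at_spec) ~
                                imputer + classifier, data = results, FUN = mean)
  structure(list(results = results, summary = summary, config = config),
            class = "experiment_report")
}

score_row <- function(rep_i, imputer, classifier, scores, y) {
  ra <- roc_auc(scores, y)
  op1 <- operating_point(ra$roc, "sensitivity", 0.85)
  op2 <- operating_point(ra$roc, "specificity", 0.85)
  data.frame(repeat_ = rep_i, imputer = imputer, classifier = classifier,
             auc = ra$auc, spec_at_sens = unname(op1["specificity"]),
             sens_at_spec = unname(op2["sensitivity"]))
}

#' @export
print.experiment_report <- function(x, ...) {
  cat(sprintf("experiment: %d repeats, imputers {%s}\n",
              x$config$n_repeats, paste(x$config$imputers, collapse = ", ")))
  cat("mean metrics over repeats:\n")
  print(x$summary, row.names = FALSE, digits = 3)
  invisible(x)
}
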