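#' Mean absolute imputation error over missing cells
#'
#' \eqn{\mathrm{MAE} = \frac{1}{N_{miss}} \sum_{(i,j) \in M} |\pi_{ij} - y_{ij}|},
#' the mean absolute difference between imputation means and true values,
#' over the masked cells only.  When the imputation carries standardization
#' statistics (as GPLVM imputations do) both sides are standardized first,
#' so the error is reported on the common zero-mean/unit-sd scale.
#'
#' @param imp An [imputed_data()] object.
#' @param truth Numeric matrix of true values (same shape and scale as the
#'   data that was imputed).
#' @param standardized Standardize with `imp$train_stats` before averaging
#'   (default `TRUE`; ignored when no statistics are stored).
#' @return Scalar MAE.
#' @export
imputation_mae <- function(imp, truth, standardized = TRUE) {
  stopifnot(inherits(imp, "imputed_data"))
  truth <- as.matrix(truth)
  stopifnot(identical(dim(truth), dim(imp$values)))
  if (imp$n_miss == 0L)
    stop("MAE is undefined with no missing cells", call. = FALSE)
  est <- imp$values; tru <- truth
  if (standardized && !is.null(imp$train_stats)) {
    sdv <- imp$train_stats$sd; mu <- imp$train_stats$mean
    est <- sweep(sweep(est, 2, mu, "-"), 2, sdv, "/")
    tru <- sweep(sweep(tru, 2, mu, "-"), 2, sdv, "/")
  }
  mean(abs(est[imp$mask] - tru[imp$mask]))
}

#' Coverage of the imputation confidence bounds
#'
#' Fraction of masked cells whose true value lies inside
#' \eqn{\pi_{ij} \pm 2\sigma_{ij}} (boundary counts as covered).  For a
#' calibrated Gaussian imputation the expected coverage is the two-sigma
#' Gaussian mass, about 0.954.
#'
#' @inheritParams imputation_mae
#' @param k Half-width of the bound in standard deviations (default 2).
#' @return Proportion in `[0, 1]`.
#' @export
imputation_coverage <- function(imp, truth, k = 2) {
  stopifnot(inherits(imp, "imputed_data"))
  truth <- as.matrix(truth)
  stopifnot(identical(dim(truth), dim(imp$values)))
  if (imp$n_miss == 0L)
    stop("coverage is undefined with no missing cells", call. = FALSE)
  m <- imp$mask
  mean(abs(truth[m] - imp$values[m]) <= k * imp$sd[m])
}

#' ROC curve and AUC
#'
#' Builds the empirical ROC curve (tied scores grouped, so ties produce
#' diagonal segments) and its trapezoidal area, which equals the
#' Mann-Whitney probability that a random positive outscores a random
#' negative with half credit for ties.
#'
#' @param scores Numeric decision scores, larger = more positive.
#' @param labels Labels (coerced to -1/+1).
#' @return List with `roc` (data frame of `fpr`, `tpr` from (0,0) to (1,1))
#'   and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  y <- svm_labels(labels)
  stopifnot(length(scores) == length(y), all(is.finite(scores)))
  npos <- sum(y > 0); nneg <- sum(y < 0)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; yy <- y[ord]
  grp <- cumsum(!duplicated(s))          # tie groups in descending order
  tp <- cumsum(yy > 0); fp <- cumsum(yy < 0)
  last <- !duplicated(grp, fromLast = TRUE)
  tpr <- c(0, tp[last] / npos); fpr <- c(0, fp[last] / nneg)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' True positive rate at fixed false positive rates
#'
#' Linear interpolation of the ROC polyline at each requested FPR.
#'
#' @param roc A `roc` data frame from [roc_auc()] (columns `fpr`, `tpr`).
#' @param fpr_grid FPR values in `[0, 1]` (default 0.1, ..., 0.9).
#' @return Named numeric vector of interpolated TPRs.
#' @export
tpr_at_fpr <- function(roc, fpr_grid = seq(0.1, 0.9, by = 0.1)) {
  if (is.list(roc) && !is.data.frame(roc) && !is.null(roc$roc)) roc <- roc$roc
  if (any(fpr_grid < 0 | fpr_grid > 1))
    stop("fpr values must lie in [0, 1]", call. = FALSE)
  out <- stats::approx(roc$fpr, roc$tpr, xout = fpr_grid, ties = max,
                       rule = 2)$y
  stats::setNames(out, paste0("fpr", fpr_grid))
}

#' Operating point at fixed sensitivity or specificity
#'
#' Reads the ROC at a clinically fixed level: with sensitivity fixed, the
#' achievable specificity is interpolated (and vice versa).  High
#' sensitivity rules the outcome out; high specificity rules it in.
#'
#' @param roc A `roc` data frame (or [roc_auc()] result).
#' @param fix `"sensitivity"` or `"specificity"`.
#' @param level The fixed level, in (0, 1); default 0.85.
#' @return Named vector `c(sensitivity=, specificity=)`.
#' @export
operating_point <- function(roc, fix = c("sensitivity", "specificity"),
                            level = 0.85) {
  fix <- match.arg(fix)
  if (is.list(roc) && !is.data.frame(roc) && !is.null(roc$roc)) roc <- roc$roc
  if (level <= 0 || level >= 1)
    stop("level must be in (0, 1)", call. = FALSE)
  if (fix == "sensitivity") {
    fpr <- stats::approx(roc$tpr, roc$fpr, xout = level, ties = min,
                         rule = 2)$y
    c(sensitivity = level, specificity = 1 - fpr)
  } else {
    tpr <- stats::approx(roc$fpr, roc$tpr, xout = 1 - level, ties = max,
                         rule = 2)$y
    c(sensitivity = tpr, specificity = level)
  }
}

#' Stratified bootstrap confidence interval for a score-based metric
#'
#' Percentile interval from case resampling stratified by class: each
#' replicate resamples positives and negatives separately with replacement,
#' so every replicate contains both classes.
#'
#' @param metric_fn Function `(scores, labels) -> scalar`.
#' @param scores,labels The observed scores and labels.
#' @param n_boot Number of bootstrap replicates (`>= 100`; default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed.
#' @return Named vector `c(lo=, hi=)`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, n_boot = 1000,
                         level = 0.95, seed = 1) {
  stopifnot(n_boot >= 100)
  y <- svm_labels(labels)
  pos <- which(y > 0); neg <- which(y < 0)
  stat <- with_seed(derive_seed(seed, "bootstrap"), {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(pos, length(pos), replace = TRUE),
               sample(neg, length(neg), replace = TRUE))
      metric_fn(scores[idx], y[idx])
    }, numeric(1))
  })
  a <- (1 - level) / 2
  qs <- stats::quantile(stat, c(a, 1 - a), names = FALSE, type = 7)
  c(lo = qs[1], hi = qs[2])
}

#' Full classifier evaluation report
#'
#' ROC curve, AUC with bootstrap CI, the TPR-at-FPR table, and operating
#' points at fixed sensitivity and specificity with bootstrap CIs.
#'
#' @param scores,labels Decision scores and labels.
#' @param fpr_grid FPR grid for the TPR table.
#' @param op_level Fixed level for the operating points (default 0.85).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param level Confidence level (default 0.95).
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `eval_report`.
#' @export
evaluate_classifier <- function(scores, labels,
                                fpr_grid = seq(0.1, 0.9, by = 0.1),
                                op_level = 0.85, n_boot = 1000, level = 0.95,
                                seed = 1) {
  y <- svm_labels(labels)
  ra <- roc_auc(scores, y)
  auc_ci <- bootstrap_ci(function(s, l) roc_auc(s, l)$auc, scores, y,
                         n_boot = n_boot, level = level, seed = seed)
  op_sens <- operating_point(ra$roc, "sensitivity", op_level)
  op_spec <- operating_point(ra$roc, "specificity", op_level)
  spec_ci <- bootstrap_ci(function(s, l)
    operating_point(roc_auc(s, l)$roc, "sensitivity", op_level)["specificity"],
    scores, y, n_boot = n_boot, level = level, seed = seed)
  sens_ci <- bootstrap_ci(function(s, l)
    operating_point(roc_auc(s, l)$roc, "specificity", op_level)["sensitivity"],
    scores, y, n_boot = n_boot, level = level, seed = seed)
  structure(list(
    roc = ra$roc, auc = ra$auc, auc_ci = auc_ci,
    tpr_at_fpr = tpr_at_fpr(ra$roc, fpr_grid),
    op_points = list(
      fixed_sensitivity = list(point = op_sens, specificity_ci = spec_ci),
      fixed_specificity = list(point = op_spec, sensitivity_ci = sens_ci)),
    op_level = op_level, n = length(y), n_pos = sum(y > 0)
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("classifier evaluation: n = %d (%d positives)\n", x$n, x$n_pos))
  cat(sprintf("  AUC = %.3f (95%% CI %.3f, %.3f)\n", x$auc, x$auc_ci["lo"],
              x$auc_ci["hi"]))
  cat("  TPR at FPR grid:\n")
  print(round(x$tpr_at_fpr, 3))
  fs <- x$op_points$fixed_sensitivity; fp <- x$op_points$fixed_specificity
  cat(sprintf("  at sensitivity %.2f: specificity = %.3f (CI %.3f, %.3f)\n",
              x$op_level, fs$point["specificity"], fs$specificity_ci["lo"],
              fs$specificity_ci["hi"]))
  cat(sprintf("  at specificity %.2f: sensitivity = %.3f (CI %.3f, %.3f)\n",
              x$op_level, fp$point["sensitivity"], fp$sensitivity_ci["lo"],
              fp$sensitivity_ci["hi"]))
  invisible(x)
}
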