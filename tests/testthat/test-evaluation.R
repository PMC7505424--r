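test_that("MAE and coverage match loop-based oracles", {
  set.seed(1)
  vals <- matrix(rnorm(200), 20, 10)
  truth <- vals + matrix(rnorm(200, sd = 0.5), 20, 10)
  mask <- matrix(runif(200) < 0.3, 20, 10)
  sdm <- matrix(0, 20, 10); sdm[mask] <- runif(sum(mask), 0.2, 1)
  imp <- imputed_data(vals, sdm, mask, method = "test")
  ## brute-force loops
  errs <- c(); cov <- c()
  for (i in 1:20) for (j in 1:10) if (mask[i, j]) {
    errs <- c(errs, abs(vals[i, j] - truth[i, j]))
    cov <- c(cov, abs(truth[i, j] - vals[i, j]) <= 2 * sdm[i, j])
  }
  expect_equal(imputation_mae(imp, truth), mean(errs))
  expect_equal(imputation_coverage(imp, truth), mean(cov))
  ## exact-cases
  expect_equal(imputation_mae(imputed_data(truth, sdm, mask), truth), 0)
  one <- imputed_data(matrix(1.5), matrix(0.1), matrix(TRUE))
  expect_equal(imputation_mae(one, matrix(1.0)), 0.5)
  expect_equal(imputation_coverage(
    imputed_data(matrix(0), matrix(1), matrix(TRUE)), matrix(3)), 0)
  full <- imputed_data(vals, matrix(0, 20, 10), matrix(FALSE, 20, 10))
  expect_error(imputation_mae(full, truth), "undefined")
  expect_error(imputation_coverage(full, truth), "undefined")
})

test_that("coverage of a calibrated Gaussian imputation is the two-sigma
          mass", {
  set.seed(2)
  n <- 100; m <- 100
  vals <- matrix(rnorm(n * m), n, m)
  sdm <- matrix(runif(n * m, 0.5, 2), n, m)
  mask <- matrix(TRUE, n, m)
  truth <- vals + sdm * matrix(rnorm(n * m), n, m)
  imp <- imputed_data(vals, sdm, mask)
  expect_equal(imputation_coverage(imp, truth), 2 * pnorm(2) - 1,
               tolerance = 0.01)
})

test_that("AUC equals the all-pairs concordance count, with edge cases", {
  set.seed(3)
  s <- round(rnorm(30), 1)               # rounding forces ties
  y <- sign(rnorm(30)); y[y == 0] <- 1
  while (length(unique(y)) < 2) y <- sign(rnorm(30))
  ra <- roc_auc(s, y)
  pos <- s[y > 0]; neg <- s[y < 0]
  brute <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_equal(ra$auc, brute)
  ## perfect and reversed rankings
  expect_equal(roc_auc(c(3, 4, 1, 2), c(1, 1, -1, -1))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, -1, -1))$auc, 0)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "two classes")
  ## invariance under strictly monotone transforms
  s2 <- exp(2 * s)
  expect_equal(roc_auc(s2, y)$auc, ra$auc)
  ## ROC endpoints and monotonicity
  expect_equal(unlist(ra$roc[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(ra$roc[nrow(ra$roc), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(ra$roc$fpr) >= 0) && all(diff(ra$roc$tpr) >= 0))
})

test_that("TPR interpolation and operating points follow the polyline", {
  toy <- data.frame(fpr = c(0, 0.5, 1), tpr = c(0, 1, 1))
  expect_equal(unname(tpr_at_fpr(toy, c(0.25, 1))), c(0.5, 1))
  expect_error(tpr_at_fpr(toy, 1.2), "\\[0, 1\\]")
  expect_equal(unname(operating_point(toy, "specificity", 0.85)["sensitivity"]),
               0.3)
  ## perfect classifier: fixing sensitivity gives specificity 1
  perfect <- roc_auc(c(2, 3, 0, 1), c(1, 1, -1, -1))$roc
  expect_equal(unname(operating_point(perfect, "sensitivity", 0.85)["specificity"]),
               1)
  ## chance diagonal: specificity = 1 - level
  diag_roc <- data.frame(fpr = c(0, 1), tpr = c(0, 1))
  expect_equal(unname(operating_point(diag_roc, "sensitivity", 0.85)["specificity"]),
               0.15)
  expect_error(operating_point(toy, "sensitivity", 1.2), "level")
})

test_that("bootstrap intervals are reproducible, degenerate for constant
          metrics, and calibrated for the AUC", {
  set.seed(4)
  s <- c(rnorm(40, 1), rnorm(40)); y <- rep(c(1, -1), each = 40)
  ci1 <- bootstrap_ci(function(a, b) roc_auc(a, b)$auc, s, y,
                      n_boot = 200, seed = 5)
  ci2 <- bootstrap_ci(function(a, b) roc_auc(a, b)$auc, s, y,
                      n_boot = 200, seed = 5)
  expect_identical(ci1, ci2)
  expect_true(ci1["lo"] <= ci1["hi"])
  const <- bootstrap_ci(function(a, b) 0.7, s, y, n_boot = 100, seed = 1)
  expect_equal(unname(const), c(0.7, 0.7))
  expect_error(bootstrap_ci(function(a, b) 1, s, y, n_boot = 10), "n_boot")

  ## calibration: interval covers the true AUC at roughly the nominal rate
  truth <- pnorm(1 / sqrt(2))    # AUC of N(1,1) vs N(0,1) scores
  hits <- vapply(1:150, function(r) {
    set.seed(1000 + r)
    ss <- c(rnorm(60, 1), rnorm(60)); yy <- rep(c(1, -1), each = 60)
    ci <- bootstrap_ci(function(a, b) roc_auc(a, b)$auc, ss, yy,
                       n_boot = 200, seed = r)
    ci["lo"] <= truth && truth <= ci["hi"]
  }, logical(1))
  expect_equal(mean(hits), 0.95, tolerance = 0.05)
})

test_that("the full evaluation report is internally consistent", {
  set.seed(6)
  s <- c(rnorm(60, 0.8), rnorm(90)); y <- c(rep(1, 60), rep(-1, 90))
  rep_ <- evaluate_classifier(s, y, n_boot = 200, seed = 2)
  expect_s3_class(rep_, "eval_report")
  expect_true(rep_$auc_ci["lo"] <= rep_$auc && rep_$auc <= rep_$auc_ci["hi"])
  expect_equal(unname(rep_$tpr_at_fpr["fpr0.9"]),
               unname(tpr_at_fpr(rep_$roc, 0.9)))
  expect_output(print(rep_), "AUC")
})
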