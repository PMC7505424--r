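## build a small imputed dataset with genuine uncertainty
make_uncertain_imp <- function(seed, n = 40, d = 3, frac = 0.3, sd_miss = 0.6) {
  set.seed(seed)
  x <- matrix(rnorm(n * d), n, d)
  y <- sign(x[, 1] + rnorm(n, sd = 0.5)); y[y == 0] <- 1
  mask <- matrix(runif(n * d) < frac, n, d)
  sdm <- matrix(0, n, d); sdm[mask] <- sd_miss
  list(imp = imputed_data(x, sdm, mask, method = "test"), y = y)
}

test_that("an ensemble trains one member per completion, in order", {
  u <- make_uncertain_imp(1)
  cs <- sample_completions(u$imp, 3, seed = 2)
  ens <- train_ensemble(cs, u$y, C = 5, kernel_scale = 1.5)
  expect_length(ens, 3)
  ## p = 1 equals a direct fit
  e1 <- train_ensemble(cs[1], u$y, C = 5, kernel_scale = 1.5)
  direct <- kernel_svm(cs[[1]], u$y, C = 5, kernel_scale = 1.5)
  expect_equal(e1[[1]]$alpha, direct$alpha)
  ## identical completions give identical members
  e2 <- train_ensemble(list(cs[[1]], cs[[1]]), u$y, C = 5, kernel_scale = 1.5)
  expect_identical(e2[[1]]$alpha, e2[[2]]$alpha)
  ## distinct samples perturb the QP
  expect_gt(max(abs(ens[[1]]$alpha - ens[[2]]$alpha)), 1e-6)
})

test_that("zero penalty reduces the constrained SVM to the vanilla SVM", {
  for (s in 1:5) {
    u <- make_uncertain_imp(300 + s)
    cf <- constrained_svm(u$imp, u$y, p = 4, lambda = 0, C = 5,
                          kernel_scale = 1.5, seed = s)
    sv <- kernel_svm(cf$x, u$y, C = 5, kernel_scale = 1.5)
    expect_equal(cf$alpha, sv$alpha, tolerance = 1e-6)
    expect_equal(cf$b, sv$b, tolerance = 1e-6)
    probe <- matrix(rnorm(15), 5, 3)
    expect_equal(predict(cf, probe), predict(sv, probe), tolerance = 1e-6)
    expect_equal(predict(cf, probe, decision_rule = "full"),
                 predict(sv, probe), tolerance = 1e-6)
  }
})

test_that("the penalized dual matches the interior-point oracle and stays
          feasible for all lambda", {
  u <- make_uncertain_imp(9, n = 30)
  for (lam in c(0, 0.5, 1)) {
    cf <- constrained_svm(u$imp, u$y, p = 3, lambda = lam, C = 5,
                          kernel_scale = 1.5, seed = 4)
    expect_true(all(cf$alpha >= -1e-12 & cf$alpha <= 5 + 1e-12))
    expect_lt(abs(sum(cf$alpha * cf$y)), 1e-6)
    K <- missgp:::svm_kernel(cf$x, cf$x, "rbf", 1.5)
    q <- 1 + lam * cf$y * cf$W_train
    a_ip <- ipop_alpha(K, cf$y, 5, q = q)
    expect_equal(cf$objective, dual_objective(K, cf$y, a_ip, q = q),
                 tolerance = 1e-5)
  }
})

test_that("the full decision rule satisfies the KKT margin on free support
          vectors and flips with the labels", {
  u <- make_uncertain_imp(6)
  cf <- constrained_svm(u$imp, u$y, p = 3, lambda = 1, C = 5,
                        kernel_scale = 1.5, seed = 3)
  sc <- predict(cf, cf$x, decision_rule = "full")
  free <- cf$alpha > 5e-8 & cf$alpha < 5 - 5e-8
  expect_true(any(free))
  expect_equal(unname(cf$y[free] * sc[free]), rep(1, sum(free)),
               tolerance = 1e-6)
  ## label-flip antisymmetry (same completion draws)
  cf2 <- constrained_svm(u$imp, -u$y, p = 3, lambda = 1, C = 5,
                         kernel_scale = 1.5, seed = 3)
  probe <- matrix(rnorm(15), 5, 3)
  expect_equal(cf2$alpha, cf$alpha, tolerance = 1e-6)
  expect_equal(predict(cf2, probe, decision_rule = "full"),
               -predict(cf, probe, decision_rule = "full"), tolerance = 1e-5)
  expect_equal(predict(cf2, probe), -predict(cf, probe), tolerance = 1e-5)
})

test_that("kernel mismatches with the ensemble are rejected", {
  u <- make_uncertain_imp(2)
  cs <- sample_completions(u$imp, 2, seed = 1)
  ens <- train_ensemble(cs, u$y, C = 5, kernel_scale = 1.5)
  expect_error(solve_csvm_dual(cs[[1]], u$y, ens, kernel_scale = 2, C = 5),
               "match the ensemble")
  expect_error(solve_csvm_dual(cs[[1]], u$y, ens, lambda = -1, C = 5,
                               kernel_scale = 1.5), ">= 0")
})
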