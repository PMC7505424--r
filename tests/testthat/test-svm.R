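test_that("the two-point instance has the known analytic solution", {
  fit <- kernel_svm(matrix(c(-1, 1), 2, 1), c(-1, 1), C = 10,
                    kernel = "linear")
  expect_equal(fit$alpha, c(0.5, 0.5), tolerance = 1e-8)
  expect_equal(fit$b, 0, tolerance = 1e-8)
  ## margin 2/||w|| with w = sum alpha y s = 1
  w <- sum(fit$alpha * fit$y * fit$x)
  expect_equal(2 / abs(w), 2, tolerance = 1e-8)
  expect_equal(predict(fit, matrix(0)), 0, tolerance = 1e-8)
})

test_that("SMO solutions satisfy the KKT constraints and match the
          interior-point oracle", {
  for (s in 1:8) {
    inst <- rand_svm_instance(200 + s)
    K <- missgp:::svm_kernel(inst$x, inst$x, "rbf", inst$ks)
    sol <- solve_svm_dual(K, inst$y, inst$C)
    expect_true(all(sol$alpha >= -1e-12 & sol$alpha <= inst$C + 1e-12))
    expect_lt(abs(sum(sol$alpha * inst$y)), 1e-6)
    a_ip <- ipop_alpha(K, inst$y, inst$C)
    expect_equal(sol$objective, dual_objective(K, inst$y, a_ip),
                 tolerance = 1e-5)
  }
})

test_that("single-class input and bad parameters are rejected", {
  x <- matrix(rnorm(10), 5, 2)
  expect_error(kernel_svm(x, rep(1, 5)), "two classes")
  expect_error(kernel_svm(x, c(1, 1, -1, -1, 1), C = -1), "positive")
  expect_error(missgp:::svm_kernel(x, x, "rbf", 0), "positive")
})

test_that("duplicating a zero-alpha point leaves the solution unchanged", {
  inst <- rand_svm_instance(42, n = 30, C = 10)
  fit <- kernel_svm(inst$x, inst$y, C = 10, kernel_scale = inst$ks)
  zero <- which(fit$alpha < 1e-10)[1]
  x2 <- rbind(inst$x, inst$x[zero, ])
  y2 <- c(inst$y, inst$y[zero])
  fit2 <- kernel_svm(x2, y2, C = 10, kernel_scale = inst$ks)
  expect_equal(fit2$objective, fit$objective, tolerance = 1e-6)
  probe <- matrix(rnorm(10 * ncol(inst$x)), 10)
  expect_equal(predict(fit2, probe), predict(fit, probe), tolerance = 1e-4)
})

test_that("negating the labels negates the decision scores", {
  inst <- rand_svm_instance(77, n = 25, C = 5)
  f1 <- kernel_svm(inst$x, inst$y, C = 5, kernel_scale = inst$ks)
  f2 <- kernel_svm(inst$x, -inst$y, C = 5, kernel_scale = inst$ks)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-6)
  expect_equal(f2$b, -f1$b, tolerance = 1e-6)
  probe <- matrix(rnorm(8 * ncol(inst$x)), 8)
  expect_equal(predict(f2, probe), -predict(f1, probe), tolerance = 1e-6)
})

test_that("kernel-scale tuning picks the out-of-sample optimum", {
  set.seed(8)
  n <- 200
  x <- matrix(runif(n * 2, -2, 2), n, 2)
  f <- function(x) sin(2 * x[, 1]) + x[, 2]^2 - 1
  y <- sign(f(x) + rnorm(n, sd = 0.3)); y[y == 0] <- 1
  grid <- c(0.1, 0.3, 1, 3, 10)
  ks <- tune_kernel_scale(x, y, C = 10, grid = grid, seed = 2)
  ## out-of-sample sweep oracle
  set.seed(99)
  xo <- matrix(runif(2000, -2, 2), 1000, 2)
  yo <- sign(f(xo) + rnorm(1000, sd = 0.3)); yo[yo == 0] <- 1
  oos <- vapply(grid, function(k)
    roc_auc(predict(kernel_svm(x, y, C = 10, kernel_scale = k, tol = 1e-6),
                    xo), yo)$auc, numeric(1))
  best <- which.max(oos)
  expect_true(which(grid == ks) %in% (best + -1:1))
  ## degenerate grid and determinism
  expect_equal(tune_kernel_scale(x, y, grid = 2.5), 2.5)
  expect_identical(tune_kernel_scale(x, y, C = 10, grid = grid, seed = 2), ks)
})
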