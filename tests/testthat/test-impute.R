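test_that("latent inference returns the prior with no observations and is
          consistent on training rows", {
  fit <- toy_gplvm()
  Q <- fit$latent_dim
  q0 <- infer_latent(fit, rep(NA_real_, 6))
  expect_equal(q0$mean, rep(0, Q))
  expect_equal(q0$var, rep(1, Q))
  expect_error(infer_latent(fit, rep(0, 6), mask = c(TRUE, FALSE)),
               "mask length")

  ## fully observed training row: posterior mean near the training latent
  i <- 5
  qi <- infer_latent(fit, fit$Y_train[i, ], rep(FALSE, 6))
  expect_lt(max(abs(qi$mean - fit$X_mean[i, ])), 0.1)
  expect_true(all(qi$var > 0))

  ## identical rows give identical posteriors
  qj <- infer_latent(fit, fit$Y_train[i, ], rep(FALSE, 6))
  expect_identical(qi, qj)
})

test_that("imputation moments collapse to the sparse-GP predictive at a
          point and respect the noise floor", {
  fit <- toy_gplvm()
  q <- structure(list(mean = c(0.3, -0.5, 0.2), var = rep(1e-10, 3)),
                 class = "latent_posterior")
  mom <- missgp:::predictive_moments(fit, q, 1:6)
  ks <- rbf_kernel(matrix(q$mean, 1), fit$inducing_inputs,
                   fit$signal_var, fit$lengthscales)
  pm <- as.vector(ks %*% fit$pred$A)
  pv <- as.numeric(fit$signal_var - ks %*% fit$pred$Bpred %*% t(ks))
  expect_equal(mom$mean, pm, tolerance = 1e-8)
  expect_equal(mom$var, rep(pv, 6), tolerance = 1e-4)

  ## impute_row: empty mask no-op; sd floor sqrt(tau2)
  r0 <- impute_row(fit, fit$Y_train[1, ], rep(FALSE, 6))
  expect_length(r0$mean, 0)
  r1 <- impute_row(fit, fit$Y_train[1, ], c(TRUE, TRUE, rep(FALSE, 4)))
  expect_true(all(r1$sd >= sqrt(fit$noise_var) - 1e-12))
  expect_warning(r_all <- impute_row(fit, rep(NA_real_, 6)), "no observed")
  expect_equal(r_all$mean, rep(0, 6))
  expect_equal(r_all$sd, rep(sqrt(fit$signal_var + fit$noise_var), 6))
})

test_that("a strongly correlated column is imputed from its partner", {
  set.seed(4)
  x1 <- rnorm(150)
  Y <- cbind(a = x1, b = x1 + rnorm(150, sd = 0.1), c = rnorm(150))
  fit <- gplvm(Y, latent_dim = 2, n_inducing = 25, maxit = 120,
               n_restarts = 1, seed = 2)
  r <- impute_row(fit, c(1.7, NA, 0), standardized = FALSE)
  imp <- r$mean * fit$train_stats$sd[2] + fit$train_stats$mean[2]
  sd_o <- r$sd * fit$train_stats$sd[2]
  expect_lt(abs(imp - 1.7), 2 * sd_o)
  expect_lt(sd_o, 0.5)   # far tighter than the marginal sd ~ 1
})

test_that("dataset imputation copies observed cells, fills masked ones, and
          matches the per-row computation", {
  fit <- toy_gplvm()
  Y <- fit$Y_train
  Yo <- sweep(sweep(Y, 2, fit$train_stats$sd, "*"), 2,
              fit$train_stats$mean, "+")
  ## empty mask: identity
  imp0 <- predict(fit, Yo)
  expect_equal(imp0$values, Yo, tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(imp0$sd == 0))
  expect_equal(imp0$n_miss, 0L)

  ## scattered missing cells
  set.seed(9)
  Ym <- Yo
  holes <- cbind(sample(nrow(Ym), 12, replace = TRUE), sample(6, 12, replace = TRUE))
  Ym[holes] <- NA
  mm <- masked_matrix(Ym)
  imp <- predict(fit, mm)
  expect_equal(imp$n_miss, n_missing(mm))
  expect_identical(unname(imp$sd > 0), unname(imp$mask))
  expect_equal(imp$values[!imp$mask], Yo[!imp$mask])
  ## noise floor on the standardized scale
  sd_std <- sweep(imp$sd, 2, fit$train_stats$sd, "/")
  expect_true(all(sd_std[imp$mask] >= sqrt(fit$noise_var) - 1e-10))

  ## batch equals row-by-row
  i <- unique(holes[, 1])[1]
  ri <- impute_row(fit, (Ym[i, ] - fit$train_stats$mean) / fit$train_stats$sd,
                   is.na(Ym[i, ]))
  got <- (imp$values[i, imp$mask[i, ]] -
            fit$train_stats$mean[imp$mask[i, ]]) /
    fit$train_stats$sd[imp$mask[i, ]]
  expect_equal(unname(got), ri$mean, tolerance = 1e-10)

  ## single missing cell: exactly one positive sd entry
  Y1 <- Yo; Y1[2, 3] <- NA
  imp1 <- predict(fit, Y1)
  expect_equal(sum(imp1$sd > 0), 1L)
  expect_error(predict(fit, Yo[, 1:4]), "columns")
})

test_that("completion sampling preserves observed cells and reproduces
          the imputation distribution", {
  set.seed(6)
  vals <- matrix(rnorm(30), 10, 3)
  mask <- matrix(FALSE, 10, 3); mask[c(2, 14, 27)] <- TRUE
  sdm <- matrix(0, 10, 3); sdm[mask] <- c(0.5, 1, 2)
  imp <- imputed_data(vals, sdm, mask, method = "test")
  cs <- sample_completions(imp, 4, seed = 2)
  expect_length(cs, 4)
  for (m in cs) expect_equal(m[!mask], vals[!mask])
  expect_identical(cs, sample_completions(imp, 4, seed = 2))
  ## law of large numbers on one cell
  draws <- vapply(sample_completions(imp, 5000, seed = 3),
                  function(m) m[2], numeric(1))
  expect_lt(abs(mean(draws) - vals[2]), 3 * 0.5 / sqrt(5000))
  expect_equal(sd(draws), 0.5, tolerance = 0.05)
  ## zero missing: all draws identical to input
  imp0 <- imputed_data(vals, matrix(0, 10, 3), matrix(FALSE, 10, 3))
  expect_true(all(vapply(sample_completions(imp0, 3, seed = 1),
                         identical, logical(1), y = vals)))
})
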