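test_that("ELBO components behave as a variational bound should", {
  ## KL term vanishes when q(X) is the standard-normal prior
  set.seed(4)
  N <- 4
  th <- list(mu = matrix(0, N, 1), S = matrix(1, N, 1),
             Z = matrix(rnorm(3), 3, 1), l2 = 1, sf2 = 1, tau2 = 0.5)
  Y <- matrix(rnorm(N * 2), N, 2)
  r <- missgp:::elbo_core(th, Y, jitter = 1e-8)
  expect_equal(r$kl, 0)
  expect_equal(r$value, r$data_term)

  ## collapsed q at the inducing inputs recovers the exact GP marginal
  set.seed(1)
  N <- 2; Y1 <- matrix(rnorm(N), N, 1)
  mu <- matrix(rnorm(N), N, 1)
  th <- list(mu = mu, S = matrix(1e-8, N, 1), Z = mu,
             l2 = 1.5, sf2 = 1.2, tau2 = 0.4)
  r <- missgp:::elbo_core(th, Y1, jitter = 1e-10)
  K <- rbf_kernel(mu, mu, 1.2, sqrt(1.5)) + diag(0.4, N)
  logp <- as.numeric(-0.5 * N * log(2 * pi) -
                       0.5 * determinant(K)$modulus -
                       0.5 * t(Y1) %*% solve(K) %*% Y1)
  expect_equal(r$data_term, logp, tolerance = 1e-6)
})

test_that("ELBO never exceeds the quadrature-computed log evidence", {
  for (s in 1:5) {
    set.seed(s)
    N <- 3; M <- sample(1:2, 1)
    Y <- matrix(rnorm(N * M), N, M)
    th <- list(mu = matrix(rnorm(N), N, 1),
               S = matrix(runif(N, 0.1, 1), N, 1),
               Z = matrix(rnorm(2), 2, 1),
               l2 = runif(1, 0.5, 2), sf2 = runif(1, 0.5, 2),
               tau2 = runif(1, 0.2, 1))
    el <- missgp:::elbo_core(th, Y, jitter = 1e-9)$value
    lp <- quadrature_log_evidence(Y, th$l2, th$sf2, th$tau2)
    expect_lte(el, lp + 1e-6)
  }
})

test_that("fitting improves the bound and is deterministic given the seed", {
  d <- make_lowrank(60, 5, seed = 11)
  f1 <- gplvm(d$Y, latent_dim = 2, n_inducing = 10, maxit = 40,
              n_restarts = 1, seed = 3)
  f2 <- gplvm(d$Y, latent_dim = 2, n_inducing = 10, maxit = 40,
              n_restarts = 1, seed = 3)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$X_mean, f2$X_mean)
  expect_gte(f1$elbo, f1$elbo_trace[1])
  expect_true(all(is.finite(coef(f1))))
  expect_gt(f1$noise_var, 0)
  expect_error(gplvm(d$Y, latent_dim = 5), "smaller than")
})

test_that("ARD lengthscales prune unused latent dimensions", {
  set.seed(5)
  N <- 200
  X <- matrix(rnorm(N * 2), N, 2)
  K <- rbf_kernel(X, X, 1, 1)
  L <- missgp:::chol_jitter(K, 1e-8)
  Y <- crossprod(L, matrix(rnorm(N * 10), N, 10)) +
    matrix(rnorm(N * 10, sd = 0.3), N, 10)
  fit <- gplvm(Y, latent_dim = 5, n_inducing = 30, maxit = 150,
               n_restarts = 2, seed = 1)
  ls <- sort(fit$lengthscales)
  ## two dimensions carry the signal; the other three grow away
  expect_gt(ls[3], 2 * ls[2])
  expect_equal(summary(fit)$effective_dims >= 2, TRUE)
})

test_that("noise-only data recovers the sample variance as noise", {
  set.seed(3)
  Yn <- matrix(rnorm(500 * 10), 500, 10)
  fitn <- gplvm(Yn, latent_dim = 2, n_inducing = 25, maxit = 200,
                n_restarts = 2, seed = 1)
  expect_equal(fitn$noise_var, 1, tolerance = 0.2)
})

test_that("elbo() validates inputs and reports the stored bound", {
  fit <- toy_gplvm()
  e <- elbo(fit)
  expect_equal(as.numeric(e), fit$elbo, tolerance = 1e-8)
  expect_true(is.finite(attr(e, "kl")))
  ybad <- fit$Y_train
  ybad[1, 1] <- NA
  expect_error(elbo(fit, masked_matrix(ybad)), "fully observed")
})
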