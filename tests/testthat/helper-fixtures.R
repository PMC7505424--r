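## Shared fixtures, all generated in code.

## Low-rank data: Q_true-dimensional latent, linear mixing, Gaussian noise.
make_lowrank <- function(n, m_feat, q_true = 2, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * q_true), n, q_true)
  Y <- X %*% matrix(rnorm(q_true * m_feat), q_true, m_feat) +
    matrix(rnorm(n * m_feat, sd = noise_sd), n, m_feat)
  list(Y = Y, X = X)
}

## Nonlinear low-rank data: features are GP draws over a 2-D latent, which
## keeps fitted hyperparameters in a well-conditioned regime.
make_gp_data <- function(n, m_feat, q_true = 2, noise_sd = 0.3, seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * q_true), n, q_true)
  K <- rbf_kernel(X, X, 1, 1)
  L <- missgp:::chol_jitter(K, 1e-8)
  Y <- crossprod(L, matrix(rnorm(n * m_feat), n, m_feat)) +
    matrix(rnorm(n * m_feat, sd = noise_sd), n, m_feat)
  list(Y = Y, X = X)
}

## One small fitted GPLVM, fitted lazily and cached for the whole test run.
toy_gplvm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      d <- make_gp_data(120, 6, q_true = 2, noise_sd = 0.3, seed = 42)
      cache <<- gplvm(d$Y, latent_dim = 3, n_inducing = 20, maxit = 120,
                      n_restarts = 1, seed = 7)
    }
    cache
  }
})

## Random two-class SVM instance.
rand_svm_instance <- function(seed, n = NULL, d = NULL, C = NULL) {
  set.seed(seed)
  if (is.null(n)) n <- sample(10:50, 1)
  if (is.null(d)) d <- sample(2:5, 1)
  if (is.null(C)) C <- sample(c(1, 10), 1)
  x <- matrix(rnorm(n * d), n, d)
  y <- sign(x[, 1] + rnorm(n, sd = 0.6))
  y[y == 0] <- 1
  if (length(unique(y)) < 2) y[1] <- -y[1]
  list(x = x, y = y, C = C, ks = runif(1, 0.8, 2.5))
}

## Dual objective value at a feasible alpha, for oracle comparisons.
dual_objective <- function(K, y, alpha, q = NULL) {
  if (is.null(q)) q <- rep(1, length(y))
  sum(q * alpha) - 0.5 * sum(alpha * y * (K %*% (alpha * y)))
}

## Interior-point solution of the same dual via kernlab::ipop.  The
## Hessian is only PSD, so the interior-point linear systems can go
## singular for particular scalings; a small diagonal regularization
## restores solvability without moving the optimum materially, and is
## escalated only as far as needed.
ipop_alpha <- function(K, y, C, q = NULL) {
  n <- length(y)
  if (is.null(q)) q <- rep(1, n)
  Q <- (y %*% t(y)) * K
  for (reg in c(0, 1e-10, 1e-8)) {
    sol <- tryCatch(
      kernlab::ipop(c = matrix(-q, n), H = Q + diag(reg, n), A = t(y), b = 0,
                    l = matrix(0, n), u = matrix(C, n), r = 0,
                    sigf = 10, maxiter = 400),
      error = function(e) NULL)
    if (!is.null(sol)) return(as.vector(kernlab::primal(sol)))
  }
  scipy_qp_alpha(K, y, C, q)
}

## Second independent dense solver (scipy SLSQP), for the rare instance
## whose interior-point factorization goes singular in ipop.
scipy_qp_alpha <- function(K, y, C, q) {
  inp <- tempfile(fileext = ".json"); out <- tempfile(fileext = ".json")
  on.exit(unlink(c(inp, out)))
  jsonlite::write_json(list(K = K, y = y, C = C, q = q), inp,
                       digits = NA, matrix = "rowmajor")
  code <- sprintf("
import json, numpy as np
from scipy.optimize import minimize
d = json.load(open(%s))
K = np.array(d['K']); y = np.array(d['y'], float)
C = float(d['C'][0]); q = np.array(d['q'], float)
Q = np.outer(y, y) * K
n = len(y)
f = lambda a: 0.5 * a @ Q @ a - q @ a
g = lambda a: Q @ a - q
cons = [{'type': 'eq', 'fun': lambda a: a @ y, 'jac': lambda a: y}]
res = minimize(f, np.full(n, min(C, 1.0) / 2), jac=g, bounds=[(0, C)] * n,
               constraints=cons, method='SLSQP',
               options={'maxiter': 1000, 'ftol': 1e-14})
json.dump(list(res.x), open(%s, 'w'))
", deparse(inp), deparse(out))
  script <- tempfile(fileext = ".py")
  writeLines(code, script)
  status <- system2("python", script, stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(out)) stop("scipy QP oracle failed")
  unlist(jsonlite::read_json(out))
}

## Brute-force log evidence of a 1-D-latent GP model by Gauss-Hermite
## tensor quadrature over the N latent coordinates.
quadrature_log_evidence <- function(Y, l2, sf2, tau2, n_nodes = 30) {
  gh <- pracma::gaussHermite(n_nodes)
  N <- nrow(Y)
  nodes <- sqrt(2) * gh$x
  logw <- log(gh$w) - 0.5 * log(pi)
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_nodes)), N)))
  ll <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    x <- matrix(nodes[grid[g, ]], N, 1)
    K <- rbf_kernel(x, x, sf2, sqrt(l2)) + diag(tau2, N)
    cK <- chol(K)
    quad <- colSums(backsolve(cK, Y, transpose = TRUE)^2)
    ll[g] <- sum(-0.5 * N * log(2 * pi) - sum(log(diag(cK))) - 0.5 * quad)
  }
  lw <- rowSums(matrix(logw[grid], nrow(grid), N))
  m <- max(ll + lw)
  m + log(sum(exp(ll + lw - m)))
}
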