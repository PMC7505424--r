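## ---------------------------------------------------------------------------
## Variational lower bound (ELBO) of the Bayesian GPLVM.
##
## Data model, per feature column y_d (conditionally independent given the
## latent inputs X):  y_d = f_d(X) + e_d,  f_d ~ GP(0, k),  e_d ~ N(0, tau2 I).
## The latents are given a standard-normal prior and approximated by a
## factorized Gaussian q(X).  With m inducing inputs Z the collapsed sparse
## bound for one column is
##   L_d = log N(y_d; 0, tau2 I "+" Psi1 Kmm^{-1} Psi1') collapsed through the
##         psi statistics:
##       = -N/2 log(2 pi) + N/2 log(beta) - 1/2 log|P|/|Kmm|
##         - beta/2 y'y + beta^2/2 y'Psi1 P^{-1} Psi1'y
##         - beta/2 psi0 + beta/2 tr(Kmm^{-1} Psi2),
##   with beta = 1/tau2 and P = Kmm + beta Psi2,
## and ELBO = sum_d L_d - KL(q(X) || N(0, I)).
## ---------------------------------------------------------------------------

## theta: list(mu, S, Z, l2, sf2, tau2); Y: N x D standardized data.
## Returns value, its two parts, and (optionally) analytic gradients.
elbo_core <- function(theta, Y, grad = FALSE, jitter = 1e-6) {
  mu <- theta$mu; S <- theta$S; Z <- theta$Z
  l2 <- theta$l2; sf2 <- theta$sf2; tau2 <- theta$tau2
  N <- nrow(Y); D <- ncol(Y); m <- nrow(Z)
  beta <- 1 / tau2
  ps <- psi_stats(mu, S, Z, l2, sf2, per_n = grad)
  Kmm0 <- rbf_kernel(Z, Z, variance = sf2, lengthscales = sqrt(l2))
  cK <- chol_jitter(Kmm0, jitter = jitter)
  jit <- attr(cK, "jitter")
  Kmm <- Kmm0 + diag(jit, m)
  P <- Kmm + beta * ps$Psi2
  cP <- chol(P)
  Kinv <- chol2inv(cK)
  Pinv <- chol2inv(cP)
  A1 <- crossprod(ps$Psi1, Y)                  # m x D
  U1 <- Pinv %*% A1                            # m x D
  trKinvPsi2 <- sum(Kinv * ps$Psi2)
  quad <- sum(A1 * U1)
  data_term <- -N * D / 2 * log(2 * pi) + N * D / 2 * log(beta) -
    D / 2 * (logdet_from_chol(cP) - logdet_from_chol(cK)) -
    beta / 2 * sum(Y^2) + beta^2 / 2 * quad -
    D * beta / 2 * ps$psi0 + D * beta / 2 * trKinvPsi2
  kl <- 0.5 * sum(mu^2 + S - log(S) - 1)
  out <- list(value = data_term - kl, data_term = data_term, kl = kl)
  if (!grad) return(out)

  UUt <- tcrossprod(U1)                        # m x m
  G1 <- beta^2 * (Y %*% t(U1))                 # N x m
  G2 <- (D * beta / 2) * (Kinv - Pinv) - (beta^3 / 2) * UUt
  GK <- (D / 2) * (Kinv - Pinv) - (beta^2 / 2) * UUt -
    (D * beta / 2) * (Kinv %*% ps$Psi2 %*% Kinv)
  gpsi0 <- -D * beta / 2
  gbeta <- N * D / (2 * beta) - D / 2 * sum(Pinv * ps$Psi2) -
    0.5 * sum(Y^2) + beta * quad - beta^2 / 2 * sum(U1 * (ps$Psi2 %*% U1)) -
    D / 2 * ps$psi0 + D / 2 * trKinvPsi2
  bp <- psi_backprop(G1, G2, GK, gpsi0, ps, mu, S, Z, l2, sf2, Kmm0)
  ## KL gradients (ELBO = data_term - kl)
  dmu <- bp$dmu - mu
  dS <- bp$dS - 0.5 * (1 - 1 / S)
  out$grads <- list(
    dmu = dmu,
    dlogS = dS * S,
    dZ = bp$dZ,
    dlogl2 = bp$dl2 * l2,
    dlogsf2 = bp$dsf2 * sf2,
    dlogtau2 = -gbeta * beta
  )
  out
}

## Flatten/unflatten the free parameters for optim().  Variances and
## lengthscales are optimized on the log scale (unconstrained).
theta_pack <- function(theta) {
  c(as.vector(theta$mu), log(as.vector(theta$S)), as.vector(theta$Z),
    log(theta$l2), log(theta$sf2), log(theta$tau2))
}

theta_unpack <- function(par, N, Q, m) {
  i <- 0L
  mu <- matrix(par[i + seq_len(N * Q)], N, Q); i <- i + N * Q
  S <- matrix(exp(par[i + seq_len(N * Q)]), N, Q); i <- i + N * Q
  Z <- matrix(par[i + seq_len(m * Q)], m, Q); i <- i + m * Q
  l2 <- exp(par[i + seq_len(Q)]); i <- i + Q
  sf2 <- exp(par[i + 1L]); tau2 <- exp(par[i + 2L])
  list(mu = mu, S = S, Z = Z, l2 = l2, sf2 = sf2, tau2 = tau2)
}

grads_pack <- function(g) {
  c(as.vector(g$dmu), as.vector(g$dlogS), as.vector(g$dZ),
    g$dlogl2, g$dlogsf2, g$dlogtau2)
}

#' Evidence lower bound of a fitted (or hand-built) GPLVM
#'
#' Evaluates the sparse variational lower bound on `log p(Y)` at the model's
#' current parameters.  `Y` must be fully observed and on the model's
#' internal standardized scale; by default the stored training data are
#' used.  The bound's two components are attached as attributes:
#' `data_term` (the expected log-likelihood bound) and `kl` (the KL
#' divergence from the latent prior, which is zero when the variational
#' posterior equals the standard-normal prior).
#'
#' @param model A [gplvm()] fit.
#' @param Y Optional complete numeric matrix (or `masked_matrix` with empty
#'   mask) matching the model's variational posterior rows.
#' @return The ELBO (scalar), with attributes `data_term` and `kl`.
#' @export
elbo <- function(model, Y = NULL) {
  stopifnot(inherits(model, "gplvm"))
  if (is.null(Y)) Y <- model$Y_train
  if (inherits(Y, "masked_matrix")) {
    if (n_missing(Y) > 0L)
      stop("elbo() requires fully observed data", call. = FALSE)
    Y <- Y$values
  }
  Y <- as.matrix(Y)
  th <- list(mu = model$X_mean, S = model$X_var, Z = model$inducing_inputs,
             l2 = model$l2 %||% model$lengthscales^2, sf2 = model$signal_var,
             tau2 = model$noise_var)
  if (nrow(Y) != nrow(th$mu))
    stop("Y must have one row per variational posterior row", call. = FALSE)
  res <- elbo_core(th, Y, grad = FALSE, jitter = model$jitter %||% 1e-6)
  if (!is.finite(res$value))
    stop("ELBO is non-finite; the kernel matrix may be ill-conditioned. ",
         "Try a larger jitter.", call. = FALSE)
  structure(res$value, data_term = res$data_term, kl = res$kl)
}
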