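#' Squared-exponential (RBF) kernel with ARD lengthscales
#'
#' Computes the cross-covariance matrix
#' \deqn{k(x, x') = \sigma_f^2 \exp\{-\tfrac12 \sum_q (x_q - x'_q)^2 / \ell_q^2\}}
#' between two sets of points.  Per-dimension lengthscales \eqn{\ell_q}
#' implement automatic relevance determination (ARD): dimensions whose
#' lengthscale grows large stop influencing the covariance.
#'
#' @param X1,X2 Numeric matrices with `Q` columns (points in rows).
#' @param variance Signal variance \eqn{\sigma_f^2 > 0}.
#' @param lengthscales Positive scalar or length-`Q` vector \eqn{\ell}.
#' @return `nrow(X1) x nrow(X2)` covariance matrix.
#' @examples
#' rbf_kernel(matrix(0), matrix(2), variance = 1, lengthscales = 2)
#' # exp(-0.5 * (2/2)^2) = 0.6065
#' @export
rbf_kernel <- function(X1, X2, variance = 1, lengthscales = 1) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  Q <- ncol(X1)
  if (ncol(X2) != Q) stop("X1 and X2 must have the same number of columns",
                          call. = FALSE)
  if (length(lengthscales) == 1L) lengthscales <- rep(lengthscales, Q)
  if (length(lengthscales) != Q)
    stop("lengthscales must be scalar or length ncol(X1)", call. = FALSE)
  if (variance <= 0 || any(lengthscales <= 0))
    stop("kernel variance and lengthscales must be positive", call. = FALSE)
  X1s <- sweep(X1, 2, lengthscales, "/")
  X2s <- sweep(X2, 2, lengthscales, "/")
  d2 <- outer(rowSums(X1s^2), rowSums(X2s^2), "+") - 2 * tcrossprod(X1s, X2s)
  d2[d2 < 0] <- 0
  variance * exp(-0.5 * d2)
}

## ---------------------------------------------------------------------------
## Psi statistics of the ARD-RBF kernel under a factorized Gaussian
## variational distribution q(X) = prod_n N(x_n; mu_n, diag(S_n)):
##   psi0      = sum_n E_q[k(x_n, x_n)]          = N * sf2
##   Psi1[n,i] = E_q[k(x_n, z_i)]
##   Psi2[i,j] = sum_n E_q[k(x_n, z_i) k(x_n, z_j)]
## These are the closed-form moments that make the sparse variational bound
## (and the predictive moments of latent function values) tractable.
##
## mu, S: N x Q (S = marginal variances); Z: m x Q; l2: length-Q vector of
## squared lengthscales; sf2: signal variance.  When per_n = TRUE the
## N x m x m per-row Psi2 contributions are kept for gradient backprop.
## ---------------------------------------------------------------------------
## Implementation note: the per-row log Psi2 contribution for dimension q,
##   0.5 log(l2/den2) - zd2_ij/(4 l2) - (mu_n - zbar_ij)^2 / den2_n,
## is rank-structured in (n, ij): expanding the square gives
##   [0.5 log(l2/den2) - mu^2/den2]*1 + [2 mu/den2]*zbar + [-1/den2]*zbar^2
## plus an n-independent column term, so the whole N x m^2 log-matrix is a
## single coefficient-by-basis matrix product (BLAS) rather than a tensor.
psi_stats <- function(mu, S, Z, l2, sf2, per_n = FALSE) {
  mu <- as.matrix(mu); S <- as.matrix(S); Z <- as.matrix(Z)
  N <- nrow(mu); Q <- ncol(mu); m <- nrow(Z)
  m2 <- m * m
  logP1 <- matrix(0, N, m)
  coefs <- matrix(0, N, 3L * Q + 1L)
  basis <- matrix(0, 3L * Q + 1L, m2)
  colconst <- numeric(m2)
  for (q in seq_len(Q)) {
    den1 <- l2[q] + S[, q]                     # N
    dif1 <- outer(mu[, q], Z[, q], "-")        # N x m
    logP1 <- logP1 + 0.5 * (log(l2[q]) - log(den1)) - 0.5 * dif1^2 / den1
    den2 <- l2[q] + 2 * S[, q]                 # N
    zbar <- as.vector(outer(Z[, q], Z[, q], "+") / 2)       # m^2
    zd2 <- as.vector(outer(Z[, q], Z[, q], "-")^2)          # m^2
    k <- 3L * (q - 1L)
    coefs[, k + 1L] <- 0.5 * (log(l2[q]) - log(den2)) - mu[, q]^2 / den2
    coefs[, k + 2L] <- 2 * mu[, q] / den2
    coefs[, k + 3L] <- -1 / den2
    basis[k + 1L, ] <- 1
    basis[k + 2L, ] <- zbar
    basis[k + 3L, ] <- zbar^2
    colconst <- colconst - zd2 / (4 * l2[q])
  }
  coefs[, 3L * Q + 1L] <- 1
  basis[3L * Q + 1L, ] <- colconst
  Psi1 <- sf2 * exp(logP1)
  Psi2n <- sf2^2 * exp(coefs %*% basis)        # N x m^2
  Psi2 <- matrix(colSums(Psi2n), m, m)
  out <- list(psi0 = N * sf2, Psi1 = Psi1, Psi2 = Psi2)
  if (per_n) out$Psi2n <- Psi2n
  out
}

## Backpropagate gradients of a scalar objective F through the psi
## statistics and the inducing-point Gram matrix.
##   G1 = dF/dPsi1 (N x m), G2 = dF/dPsi2 (m x m, symmetric),
##   GK = dF/dKmm (m x m, symmetric), gpsi0 = dF/dpsi0,
##   ps = psi_stats(..., per_n = TRUE), Kmm = kernel WITHOUT jitter.
## Returns gradients w.r.t. mu, S, Z (matrices) and l2, sf2 (via their
## natural scale; callers chain to log-scale).
psi_backprop <- function(G1, G2, GK, gpsi0, ps, mu, S, Z, l2, sf2, Kmm) {
  N <- nrow(mu); Q <- ncol(mu); m <- nrow(Z)
  H1 <- G1 * ps$Psi1                           # N x m
  H2 <- ps$Psi2n * rep(as.vector(G2), each = N)  # N x m^2
  HK <- GK * Kmm                               # m x m
  dmu <- matrix(0, N, Q); dS <- matrix(0, N, Q); dZ <- matrix(0, m, Q)
  dl2 <- numeric(Q)
  rs1 <- rowSums(H1); sumH1 <- sum(rs1)
  h_n <- rowSums(H2)                           # N  (sum over i,j)
  S_H <- sum(h_n)
  Hm <- matrix(colSums(H2), m, m)              # m x m (sum over n)
  rHK <- rowSums(HK)
  for (q in seq_len(Q)) {
    ## --- Psi1 chain ---
    den1 <- l2[q] + S[, q]
    H1z <- as.vector(H1 %*% Z[, q])
    H1z2 <- as.vector(H1 %*% Z[, q]^2)
    quad1 <- mu[, q]^2 * rs1 - 2 * mu[, q] * H1z + H1z2   # sum_i H1*(mu-z)^2
    dmu[, q] <- dmu[, q] - (mu[, q] * rs1 - H1z) / den1
    dS[, q] <- dS[, q] - 0.5 * rs1 / den1 + 0.5 * quad1 / den1^2
    dZ[, q] <- dZ[, q] + as.vector(crossprod(H1, mu[, q] / den1)) -
      Z[, q] * as.vector(crossprod(H1, 1 / den1))
    dl2[q] <- dl2[q] + 0.5 * sumH1 / l2[q] - 0.5 * sum(rs1 / den1) +
      0.5 * sum(quad1 / den1^2)
    ## --- Psi2 chain ---
    den2 <- l2[q] + 2 * S[, q]
    zbar_v <- as.vector(outer(Z[, q], Z[, q], "+") / 2)
    zd2 <- outer(Z[, q], Z[, q], "-")^2
    t1 <- as.vector(H2 %*% zbar_v)             # N: sum_ij H2*zbar
    t2 <- as.vector(H2 %*% zbar_v^2)           # N: sum_ij H2*zbar^2
    quad2 <- mu[, q]^2 * h_n - 2 * mu[, q] * t1 + t2
    dmu[, q] <- dmu[, q] - 2 * (mu[, q] * h_n - t1) / den2
    dS[, q] <- dS[, q] - h_n / den2 + 2 * quad2 / den2^2
    ## dZ: H2 contracted over n with weights 1 and 1/den2
    Hmu <- matrix(crossprod(H2, mu[, q] / den2), m, m)
    Hd <- matrix(crossprod(H2, 1 / den2), m, m)
    rHm <- rowSums(Hm); rHmu <- rowSums(Hmu); rHd <- rowSums(Hd)
    dZ[, q] <- dZ[, q] -
      (Z[, q] * rHm - as.vector(Hm %*% Z[, q])) / l2[q] +
      2 * rHmu - Z[, q] * rHd - as.vector(Hd %*% Z[, q])
    dl2[q] <- dl2[q] + 0.5 * S_H / l2[q] - 0.5 * sum(h_n / den2) +
      sum(Hm * zd2) / (4 * l2[q]^2) + sum(quad2 / den2^2)
    ## --- Kmm chain ---
    dZ[, q] <- dZ[, q] - 2 * (Z[, q] * rHK - as.vector(HK %*% Z[, q])) / l2[q]
    dl2[q] <- dl2[q] + sum(HK * zd2) / (2 * l2[q]^2)
  }
  dsf2 <- sumH1 / sf2 + 2 * S_H / sf2 + sum(HK) / sf2 + gpsi0 * N
  list(dmu = dmu, dS = dS, dZ = dZ, dl2 = dl2, dsf2 = dsf2)
}
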