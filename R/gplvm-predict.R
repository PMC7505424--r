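## ---------------------------------------------------------------------------
## Test-time inference for the Bayesian GPLVM: given a partially observed
## row z* = [z*_O, z*_U], optimize a Gaussian variational posterior
## q(x*) = N(mu*, diag(S*)) over the row's latent input against the bound on
## log p(z*_O | model), the training posterior held fixed; then compute the
## exact first and second moments of the latent function values on the
## missing dimensions by marginalizing over q(x*) with the closed-form psi
## statistics.  The predictive variance of an observation adds the noise
## variance tau2.
## ---------------------------------------------------------------------------

## Single-row psi statistics, using the basis matrices cached in
## model$pred (Zt = t(Z); ZB, ZB2 = vectorized pairwise inducing midpoints
## and their squares; ZD = the fixed -log contribution of inducing
## separations).  mu, S: length-Q vectors describing q(x*).
psi_row <- function(pr, mu, S, l2, sf2) {
  den1 <- l2 + S
  A1 <- mu - pr$Zt                                       # Q x m
  psi1 <- sf2 * exp(0.5 * sum(log(l2) - log(den1)) -
                      0.5 * colSums(A1^2 / den1))
  den2 <- l2 + 2 * S
  lw <- 0.5 * sum(log(l2) - log(den2)) - sum(mu^2 / den2)
  lv <- as.vector(pr$ZB %*% (2 * mu / den2)) -
    as.vector(pr$ZB2 %*% (1 / den2)) - pr$ZD
  psi2v <- sf2^2 * exp(lw + lv)                          # m^2
  list(psi1 = psi1, psi2v = psi2v, A1 = A1, den1 = den1, den2 = den2)
}

## Per-row variational objective and its analytic gradient.
## obs: indices of observed dims; z: observed values (standardized scale).
row_objective <- function(model, z, obs) {
  pr <- model$pred
  tau2 <- model$noise_var
  l2 <- model$l2 %||% model$lengthscales^2; sf2 <- model$signal_var
  Q <- model$latent_dim; m <- ncol(pr$Zt)
  No <- length(obs)
  Ao <- pr$A[, obs, drop = FALSE]
  ## Gradients of the bound w.r.t. the psi statistics are constant:
  G1 <- as.vector(Ao %*% z) / tau2                       # m
  G2v <- as.vector(-tcrossprod(Ao) + No * pr$Bpred) / (2 * tau2)  # m^2
  const <- -No / 2 * log(2 * pi * tau2) - sum(z^2) / (2 * tau2) -
    No * sf2 / (2 * tau2)                                # psi0* term
  AoAo <- tcrossprod(Ao)                                 # m x m

  list(
    value = function(par) {
      mu <- par[seq_len(Q)]; S <- exp(par[Q + seq_len(Q)])
      ps <- psi_row(pr, mu, S, l2, sf2)
      Psi2 <- matrix(ps$psi2v, m, m)
      ef <- as.vector(crossprod(ps$psi1, Ao))
      quad <- sum(AoAo * Psi2)
      kl <- 0.5 * sum(mu^2 + S - log(S) - 1)
      const + (sum(z * ef) - 0.5 * quad +
                 0.5 * No * sum(pr$Bpred * Psi2)) / tau2 - kl
    },
    grad = function(par) {
      mu <- par[seq_len(Q)]; S <- exp(par[Q + seq_len(Q)])
      ps <- psi_row(pr, mu, S, l2, sf2)
      H1 <- G1 * ps$psi1                                 # m
      H2 <- G2v * ps$psi2v                               # m^2
      h <- sum(H2)
      t1 <- as.vector(crossprod(pr$ZB, H2))              # Q
      t2 <- as.vector(crossprod(pr$ZB2, H2))             # Q
      sH1 <- sum(H1)
      A1H <- as.vector(ps$A1 %*% H1)                     # Q
      A2H <- as.vector(ps$A1^2 %*% H1)                   # Q
      quad2 <- mu^2 * h - 2 * mu * t1 + t2
      dmu <- -A1H / ps$den1 - 2 * (mu * h - t1) / ps$den2 - mu
      dS <- -0.5 * sH1 / ps$den1 + 0.5 * A2H / ps$den1^2 -
        h / ps$den2 + 2 * quad2 / ps$den2^2 -
        0.5 * (1 - 1 / S)
      c(dmu, dS * S)
    }
  )
}

#' Variational latent posterior for a partially observed row
#'
#' Optimizes a Gaussian `q(x*)` for one row against the model bound
#' restricted to the row's observed dimensions.  Optimization starts both
#' from the latent prior and from the training row nearest in
#' observed-subspace Euclidean distance; the better bound wins.  A row with
#' no observed entries returns the standard-normal prior.
#'
#' @param model A [gplvm()] fit.
#' @param row Numeric vector of length `ncol` on the model's standardized
#'   scale (use `standardized = FALSE` to pass original units).
#' @param mask Logical vector, `TRUE` = missing; defaults to `is.na(row)`.
#' @param standardized Is `row` already on the model's internal scale?
#' @return List of class `latent_posterior` with components `mean` and `var`
#'   (length-`Q` vectors, `var > 0`) and `bound` (the achieved objective).
#' @export
infer_latent <- function(model, row, mask = NULL, standardized = TRUE) {
  stopifnot(inherits(model, "gplvm"))
  row <- as.numeric(row)
  if (is.null(mask)) mask <- is.na(row)
  if (length(mask) != length(row))
    stop("mask length must equal row length", call. = FALSE)
  if (length(row) != ncol(model$Y_train))
    stop("row length must equal the number of model features", call. = FALSE)
  if (!standardized)
    row <- (row - model$train_stats$mean) / model$train_stats$sd
  obs <- which(!mask)
  Q <- model$latent_dim
  if (length(obs) == 0L) {
    return(structure(list(mean = rep(0, Q), var = rep(1, Q), bound = 0),
                     class = "latent_posterior"))
  }
  objf <- row_objective(model, row[obs], obs)
  ## start 1: prior; start 2: nearest training row in observed subspace
  d2 <- colSums((t(model$Y_train[, obs, drop = FALSE]) - row[obs])^2)
  nn <- which.min(d2)
  starts <- list(c(rep(0, Q), rep(0, Q)),
                 c(model$X_mean[nn, ], log(pmax(model$X_var[nn, ], 1e-6))))
  fn <- function(p) {
    v <- objf$value(p)
    if (length(v) != 1L || !is.finite(v)) return(1e10)
    -v
  }
  gr <- function(p) {
    g <- -objf$grad(p)
    g[!is.finite(g)] <- 0
    g
  }
  best <- NULL
  for (s in starts) {
    opt <- stats::optim(s, fn = fn, gr = gr, method = "L-BFGS-B",
                        control = list(maxit = 100, factr = 1e7))
    if (is.null(best) || -opt$value > best$bound)
      best <- list(par = opt$par, bound = -opt$value)
  }
  structure(list(mean = best$par[seq_len(Q)],
                 var = exp(best$par[Q + seq_len(Q)]),
                 bound = best$bound),
            class = "latent_posterior")
}

#' @export
print.latent_posterior <- function(x, ...) {
  cat("latent posterior q(x*):\n  mean:",
      paste(sprintf("%.3f", x$mean), collapse = " "),
      "\n  var: ", paste(sprintf("%.3f", x$var), collapse = " "), "\n")
  invisible(x)
}

#' Impute the missing entries of a single row
#'
#' Computes the exact predictive moments of the missing dimensions given the
#' observed ones: the latent posterior from [infer_latent()] is marginalized
#' through the sparse GP using closed-form psi statistics (no sampling), and
#' the observation-noise variance is added, so every reported variance is at
#' least the fitted noise variance.  A row with no observed entries is
#' imputed from the prior (mean 0, variance signal + noise, standardized
#' scale) with a warning.
#'
#' @inheritParams infer_latent
#' @return List with `mean` and `sd` vectors over the missing dimensions (in
#'   mask order), on the standardized scale, plus the `posterior` used.
#' @export
impute_row <- function(model, row, mask = NULL, standardized = TRUE) {
  row <- as.numeric(row)
  if (is.null(mask)) mask <- is.na(row)
  if (!any(mask))
    return(list(mean = numeric(0), sd = numeric(0), posterior = NULL))
  if (all(mask)) {
    warning("row has no observed entries; imputing from the latent prior")
    q <- structure(list(mean = rep(0, model$latent_dim),
                        var = rep(1, model$latent_dim), bound = 0),
                   class = "latent_posterior")
    v <- model$signal_var + model$noise_var
    return(list(mean = rep(0, sum(mask)), sd = rep(sqrt(v), sum(mask)),
                posterior = q))
  }
  q <- infer_latent(model, row, mask, standardized = standardized)
  mom <- predictive_moments(model, q, which(mask))
  list(mean = mom$mean, sd = sqrt(mom$var + model$noise_var), posterior = q)
}

## Moments of the latent function values h*_d, d in `dims`, under q(x*):
##   E[h_d]   = psi1*' A_d
##   Var[h_d] = psi0* - tr(Bpred Psi2*) + A_d' Psi2* A_d - E[h_d]^2
predictive_moments <- function(model, q, dims) {
  ps <- psi_stats(matrix(q$mean, 1), matrix(q$var, 1),
                  model$inducing_inputs, model$l2 %||% model$lengthscales^2,
                  model$signal_var)
  Ad <- model$pred$A[, dims, drop = FALSE]
  em <- as.vector(crossprod(ps$Psi1[1, ], Ad))
  common <- ps$psi0 - sum(model$pred$Bpred * ps$Psi2)
  vquad <- colSums(Ad * (ps$Psi2 %*% Ad)) - em^2
  list(mean = em, var = pmax(common + vquad, 0))
}

#' Impute all missing entries of a dataset with a fitted GPLVM
#'
#' Runs per-row latent inference and imputation for every incomplete row.
#' Observed entries are copied verbatim; each missing cell receives its
#' predictive mean and standard deviation (noise variance included).
#' Standardization is applied with the training statistics and results are
#' returned on the original data scale.
#'
#' @param object A [gplvm()] fit.
#' @param newdata A [masked_matrix()] (or numeric matrix with `NA`s) whose
#'   columns match the training columns.
#' @param ... Unused.
#' @return An [imputed_data()] object.
#' @export
predict.gplvm <- function(object, newdata, ...) {
  if (!inherits(newdata, "masked_matrix")) newdata <- masked_matrix(newdata)
  if (ncol(newdata$values) != length(object$train_stats$columns))
    stop("newdata has ", ncol(newdata$values), " columns but the model was ",
         "trained on ", length(object$train_stats$columns), call. = FALSE)
  vals <- newdata$values
  mask <- newdata$mask
  mu_c <- object$train_stats$mean; sd_c <- object$train_stats$sd
  Ystd <- sweep(sweep(vals, 2, mu_c, "-"), 2, sd_c, "/")
  out_mean <- Ystd; out_sd <- matrix(0, nrow(vals), ncol(vals))
  rows <- which(rowSums(mask) > 0L)
  for (i in rows) {
    r <- impute_row(object, Ystd[i, ], mask[i, ], standardized = TRUE)
    out_mean[i, mask[i, ]] <- r$mean
    out_sd[i, mask[i, ]] <- r$sd
  }
  values <- sweep(sweep(out_mean, 2, sd_c, "*"), 2, mu_c, "+")
  values[!mask] <- vals[!mask]  # observed cells verbatim
  sd_out <- sweep(out_sd, 2, sd_c, "*")
  dimnames(values) <- dimnames(vals)
  imputed_data(values, sd_out, mask, train_stats = object$train_stats,
               method = "gplvm")
}
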