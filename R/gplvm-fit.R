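#' Fit a Bayesian GPLVM by sparse variational inference
#'
#' Learns a low-dimensional latent embedding of a fully observed feature
#' table.  Each feature column is modelled as a noisy draw from a Gaussian
#' process over shared latent inputs with a squared-exponential ARD kernel;
#' the latent inputs carry a standard-normal prior and are approximated by a
#' factorized Gaussian variational posterior.  Hyperparameters (signal
#' variance, per-latent-dimension lengthscales, noise variance), inducing
#' inputs and the variational posterior are all estimated jointly by
#' maximizing the evidence lower bound with L-BFGS-B and analytic gradients.
#'
#' The fitted model imputes missing entries of new (or the same) rows as
#' Gaussian distributions via [predict.gplvm()]: the mean is the estimate and
#' the standard deviation quantifies the imputation uncertainty.
#'
#' @param Y A numeric matrix or [masked_matrix()].  Only fully observed rows
#'   are used for training (a message is emitted if incomplete rows are
#'   dropped).
#' @param latent_dim Number of latent dimensions `Q` (default 5).  ARD
#'   lengthscales prune dimensions the data do not support, so a generous
#'   `Q` is safe; must satisfy `Q < ncol(Y)`.
#' @param n_inducing Number of inducing inputs `m`; default
#'   `min(50, floor(N/2))`, capped at `N`.
#' @param standardize Standardize columns to zero mean / unit sd before
#'   fitting (default `TRUE`).  The statistics are stored and re-applied at
#'   prediction time.
#' @param maxit L-BFGS-B iteration budget per restart (default 200).
#' @param n_restarts Number of optimizer restarts from perturbed
#'   initializations (default 2); the restart with the best bound wins.
#' @param seed Integer seed controlling initialization; the fit is fully
#'   deterministic given `seed`.
#' @param init_noise_var Initial observation-noise variance (default 0.1 in
#'   standardized units).
#' @param jitter Diagonal jitter added to kernel matrices before
#'   factorization (default `1e-6`, escalated tenfold up to `1e-3` on
#'   failure).
#' @return An object of class `gplvm` with components `X_mean`, `X_var`
#'   (variational posterior over training latents), `inducing_inputs`,
#'   `lengthscales`, `signal_var`, `noise_var`, `train_stats`, `elbo`,
#'   `elbo_trace` and cached predictive quantities.
#' @seealso [predict.gplvm()], [elbo()], [infer_latent()]
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60 * 2), 60, 2)
#' Y <- cbind(X %*% matrix(rnorm(8), 2, 4)) + matrix(rnorm(240, sd = .3), 60, 4)
#' fit <- gplvm(Y, latent_dim = 2, n_inducing = 15, maxit = 50, seed = 1)
#' fit
#' @export
gplvm <- function(Y, latent_dim = 5, n_inducing = NULL, standardize = TRUE,
                  maxit = 200, n_restarts = 2, seed = 1,
                  init_noise_var = 0.1, jitter = 1e-6) {
  if (inherits(Y, "masked_matrix")) {
    keep <- complete_rows(Y)
    if (!all(keep)) message("gplvm: dropping ", sum(!keep),
                            " incomplete rows for training")
    Y <- Y$values[keep, , drop = FALSE]
  }
  Y <- as.matrix(Y)
  if (anyNA(Y)) stop("training data must be fully observed", call. = FALSE)
  N <- nrow(Y); M <- ncol(Y); Q <- as.integer(latent_dim)
  if (Q >= M) stop("latent_dim must be smaller than the number of features",
                   call. = FALSE)
  if (Q < 1L) stop("latent_dim must be >= 1", call. = FALSE)
  cn <- colnames(Y) %||% paste0("V", seq_len(M))

  if (standardize) {
    mu_c <- colMeans(Y); sd_c <- apply(Y, 2, stats::sd)
    if (any(sd_c == 0))
      stop("constant column(s): ", paste(cn[sd_c == 0], collapse = ", "),
           call. = FALSE)
  } else {
    mu_c <- rep(0, M); sd_c <- rep(1, M)
  }
  train_stats <- list(mean = stats::setNames(mu_c, cn),
                      sd = stats::setNames(sd_c, cn), columns = cn)
  Ys <- sweep(sweep(Y, 2, mu_c, "-"), 2, sd_c, "/")

  m <- as.integer(n_inducing %||% min(50L, max(2L, floor(N / 2))))
  m <- min(m, N)
  if (m < 2L) stop("need at least 2 inducing points", call. = FALSE)

  ## PCA initialization of the latent means, whitened per dimension
  pc <- stats::prcomp(Ys, center = FALSE, scale. = FALSE)
  nv <- min(Q, ncol(pc$x))
  X0 <- matrix(0, N, Q)
  X0[, seq_len(nv)] <- pc$x[, seq_len(nv), drop = FALSE]
  sds <- apply(X0, 2, stats::sd)
  sds[sds < 1e-8] <- 1
  X0 <- sweep(X0, 2, sds, "/")

  best <- NULL
  for (r in seq_len(max(1L, n_restarts))) {
    init <- with_seed(derive_seed(seed, paste0("gplvm-init-", r)), {
      Xr <- X0 + if (r == 1L) 0 else matrix(stats::rnorm(N * Q, sd = 0.2 * (r - 1)), N, Q)
      Zr <- Xr[sample.int(N, m), , drop = FALSE] +
        matrix(stats::rnorm(m * Q, sd = 0.01), m, Q)
      list(mu = Xr, S = matrix(0.1, N, Q), Z = Zr,
           l2 = rep(1, Q), sf2 = 1, tau2 = init_noise_var)
    })
    tr_env <- new.env(); tr_env$vals <- numeric(0)
    fn <- function(p) {
      th <- theta_unpack(p, N, Q, m)
      v <- tryCatch(elbo_core(th, Ys, grad = FALSE, jitter = jitter)$value,
                    error = function(e) -Inf)
      if (length(v) != 1L || !is.finite(v)) return(1e10)
      tr_env$vals <- c(tr_env$vals, v)
      -v
    }
    gr <- function(p) {
      th <- theta_unpack(p, N, Q, m)
      g <- tryCatch(elbo_core(th, Ys, grad = TRUE, jitter = jitter)$grads,
                    error = function(e) NULL)
      if (is.null(g)) return(rep(0, length(p)))
      g <- -grads_pack(g)
      g[!is.finite(g)] <- 0
      g
    }
    opt <- stats::optim(theta_pack(init), fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e7))
    ## when the iteration cap interrupts a line search the value optim
    ## reports can disagree with the returned parameters; re-evaluate
    val <- elbo_core(theta_unpack(opt$par, N, Q, m), Ys, grad = FALSE,
                     jitter = jitter)$value
    cand <- list(par = opt$par, value = val, trace = c(tr_env$vals, val),
                 convergence = opt$convergence, restart = r)
    if (is.null(best) || cand$value > best$value) best <- cand
  }
  if (length(best$trace) && best$value < best$trace[1] - 1e-8)
    warning("optimizer failed to improve the bound; returning best model")

  th <- theta_unpack(best$par, N, Q, m)
  model <- structure(list(
    latent_dim = Q,
    X_mean = th$mu, X_var = th$S,
    inducing_inputs = th$Z,
    lengthscales = sqrt(th$l2),
    l2 = th$l2,
    signal_var = th$sf2,
    noise_var = th$tau2,
    train_stats = train_stats,
    Y_train = Ys,
    elbo = best$value,
    elbo_trace = best$trace,
    convergence = best$convergence,
    restart_used = best$restart,
    jitter = jitter,
    seed = seed,
    call = match.call()
  ), class = "gplvm")
  model$pred <- gplvm_pred_cache(model)
  model
}

## Cache the quantities needed for prediction:
##   A:     m x D matrix with E[f_d(x*)] = psi1(x*)' A[, d]
##   Bpred: Kmm^{-1} - P^{-1}, giving Var[f(x*)] = k** - k*m' Bpred k*m
gplvm_pred_cache <- function(model) {
  Z <- model$inducing_inputs; l2 <- model$l2 %||% model$lengthscales^2
  sf2 <- model$signal_var; beta <- 1 / model$noise_var
  ps <- psi_stats(model$X_mean, model$X_var, Z, l2, sf2)
  Kmm0 <- rbf_kernel(Z, Z, variance = sf2, lengthscales = sqrt(l2))
  cK <- chol_jitter(Kmm0, jitter = model$jitter %||% 1e-6)
  Kmm <- Kmm0 + diag(attr(cK, "jitter"), nrow(Z))
  P <- Kmm + beta * ps$Psi2
  Pinv <- chol2inv(chol(P))
  Kinv <- chol2inv(cK)
  A1 <- crossprod(ps$Psi1, model$Y_train)
  ## single-row psi-statistic basis: for a test point, log Psi2* is linear
  ## in functions of q(x*) with these fixed inducing-point matrices
  m <- nrow(Z); Q <- ncol(Z)
  ZB <- matrix(0, m * m, Q); ZD <- numeric(m * m)
  for (q in seq_len(Q)) {
    ZB[, q] <- as.vector(outer(Z[, q], Z[, q], "+") / 2)
    ZD <- ZD + as.vector(outer(Z[, q], Z[, q], "-")^2) / (4 * l2[q])
  }
  list(A = beta * (Pinv %*% A1), Bpred = Kinv - Pinv,
       Zt = t(Z), ZB = ZB, ZB2 = ZB^2, ZD = ZD)
}

#' @export
print.gplvm <- function(x, ...) {
  cat("Bayesian GPLVM (sparse variational fit)\n")
  cat(sprintf("  training rows: %d   features: %d   latent dims: %d   inducing points: %d\n",
              nrow(x$Y_train), ncol(x$Y_train), x$latent_dim,
              nrow(x$inducing_inputs)))
  cat(sprintf("  ELBO: %.3f   noise sd: %.4f   signal sd: %.4f\n",
              x$elbo, sqrt(x$noise_var), sqrt(x$signal_var)))
  cat("  ARD lengthscales:", paste(sprintf("%.3f", x$lengthscales),
                                   collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.gplvm <- function(object, ...) {
  rel <- 1 / object$lengthscales^2
  out <- list(model = object,
              ard_relevance = rel / max(rel),
              effective_dims = sum(rel / max(rel) > 0.01))
  class(out) <- "summary.gplvm"
  out
}

#' @export
print.summary.gplvm <- function(x, ...) {
  print(x$model)
  cat("  ARD relevance (1/lengthscale^2, scaled to max 1):\n   ",
      paste(sprintf("%.4f", x$ard_relevance), collapse = " "), "\n")
  cat(sprintf("  effective latent dimensions (relevance > 0.01): %d\n",
              x$effective_dims))
  invisible(x)
}

#' @export
coef.gplvm <- function(object, ...) {
  c(stats::setNames(object$lengthscales,
                    paste0("lengthscale", seq_along(object$lengthscales))),
    signal_var = object$signal_var, noise_var = object$noise_var)
}

#' @export
logLik.gplvm <- function(object, ...) {
  structure(object$elbo, df = NA_integer_, class = "logLik")
}

#' @export
plot.gplvm <- function(x, which = c("trace", "latent"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    graphics::plot(x$elbo_trace, type = "l", xlab = "objective evaluation",
                   ylab = "ELBO", main = "GPLVM optimization trace", ...)
  } else {
    rel <- 1 / x$lengthscales^2
    d <- order(rel, decreasing = TRUE)[1:2]
    graphics::plot(x$X_mean[, d[1]], x$X_mean[, d[2]],
                   xlab = paste("latent dim", d[1]),
                   ylab = paste("latent dim", d[2]),
                   main = "Variational latent means", ...)
  }
  invisible(x)
}

#' Simulate new rows from a fitted GPLVM's generative process
#'
#' Draws latent inputs from the standard-normal prior, function values from
#' the model's sparse GP predictive at those inputs, and adds observation
#' noise.  Useful for posterior-predictive checks and for calibration
#' studies of the imputation uncertainty.
#'
#' @param object A [gplvm()] fit.
#' @param nsim Number of rows to simulate.
#' @param seed Integer seed (required for reproducibility; default 1).
#' @param standardized If `TRUE` (default) return rows on the model's
#'   internal standardized scale, otherwise on the original data scale.
#' @param ... Unused.
#' @return A numeric matrix with `nsim` rows; the drawn latent inputs are
#'   attached as attribute `"latents"`.
#' @export
simulate.gplvm <- function(object, nsim = 1, seed = 1, standardized = TRUE,
                           ...) {
  D <- ncol(object$Y_train)
  with_seed(seed, {
    Xs <- matrix(stats::rnorm(nsim * object$latent_dim), nsim,
                 object$latent_dim)
    Ks <- rbf_kernel(Xs, object$inducing_inputs, variance = object$signal_var,
                     lengthscales = object$lengthscales)
    fmean <- Ks %*% object$pred$A                       # nsim x D
    fvar <- pmax(object$signal_var - rowSums((Ks %*% object$pred$Bpred) * Ks), 0)
    Ysim <- fmean + matrix(stats::rnorm(nsim * D), nsim, D) *
      sqrt(fvar + object$noise_var)
    if (!standardized)
      Ysim <- sweep(sweep(Ysim, 2, object$train_stats$sd, "*"), 2,
                    object$train_stats$mean, "+")
    colnames(Ysim) <- object$train_stats$columns
    structure(Ysim, latents = Xs)
  })
}
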