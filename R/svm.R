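## ---------------------------------------------------------------------------
## Soft-margin kernel SVM via its dual quadratic program, solved by
## sequential minimal optimization (SMO) with second-order working-set
## selection.  The solver takes a general linear term, which is what the
## constrained SVM needs: its dual differs from the vanilla SVM dual only in
## the coefficients of the linear term.
##
## Dual (maximization form):
##   max_alpha  sum_j q_j alpha_j - 1/2 sum_jk alpha_j alpha_k y_j y_k K_jk
##   s.t. 0 <= alpha_j <= C,  sum_j alpha_j y_j = 0,
## with q_j = 1 for the vanilla SVM.
## ---------------------------------------------------------------------------

## RBF kernel of the classifier: K(s, s') = exp(-||s - s'||^2 / (2 sigma^2)),
## or the plain inner product for kernel = "linear".
svm_kernel <- function(X1, X2, kernel = "rbf", kernel_scale = 1) {
  X1 <- as.matrix(X1); X2 <- as.matrix(X2)
  if (kernel == "linear") return(tcrossprod(X1, X2))
  if (kernel_scale <= 0) stop("kernel_scale must be positive", call. = FALSE)
  d2 <- outer(rowSums(X1^2), rowSums(X2^2), "+") - 2 * tcrossprod(X1, X2)
  d2[d2 < 0] <- 0
  exp(-d2 / (2 * kernel_scale^2))
}

## SMO on a precomputed kernel matrix.  Returns alpha, bias b, the dual
## objective value, and convergence info.
smo_solve <- function(K, y, C, q = NULL, tol = 1e-8, max_iter = NULL) {
  n <- length(y)
  stopifnot(nrow(K) == n, all(y %in% c(-1, 1)))
  if (is.null(q)) q <- rep(1, n)
  if (is.null(max_iter)) max_iter <- max(20000L, 200L * n)
  alpha <- numeric(n)
  g <- -q                       # gradient of 1/2 a'Qa - q'a at a = 0
  Kd <- diag(K)
  yg <- -y * g                  # the "-y_i g_i" KKT quantities
  iter <- 0L
  repeat {
    iter <- iter + 1L
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    lo <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    if (!any(up) || !any(lo)) break
    Gmax <- max(yg[up]); i <- which(up)[which.max(yg[up])]
    Gmin <- min(yg[lo])
    if (Gmax - Gmin < tol || iter > max_iter) break
    ## second-order selection of j among violating members of I_low
    cand <- which(lo & yg < Gmax - 1e-16)
    if (!length(cand)) break
    a_ij <- Kd[i] + Kd[cand] - 2 * K[i, cand]
    a_ij[a_ij <= 0] <- 1e-12
    dec <- (Gmax - yg[cand])^2 / a_ij
    j <- cand[which.max(dec)]
    a <- Kd[i] + Kd[j] - 2 * K[i, j]
    if (a <= 0) a <- 1e-12
    t_step <- (Gmax - yg[j]) / a
    room_i <- if (y[i] > 0) C - alpha[i] else alpha[i]
    room_j <- if (y[j] > 0) alpha[j] else C - alpha[j]
    t_step <- min(t_step, room_i, room_j)
    if (t_step <= 0) break
    alpha[i] <- alpha[i] + y[i] * t_step
    alpha[j] <- alpha[j] - y[j] * t_step
    ## gradient update: g += Q[, i] dalpha_i + Q[, j] dalpha_j
    ## with dalpha_i = y_i t, dalpha_j = -y_j t and Q[, k] = y * K[, k] * y_k
    g <- g + y * t_step * (K[, i] - K[, j])
    yg <- -y * g
  }
  converged <- iter <= max_iter
  if (!converged)
    warning("SMO reached the iteration cap before meeting tolerance ", tol)
  ## bias from free support vectors; fallback: midpoint of the KKT interval
  sv_tol <- 1e-8 * C
  free <- alpha > sv_tol & alpha < C - sv_tol
  b <- if (any(free)) mean(yg[free]) else {
    up <- (y > 0 & alpha < C) | (y < 0 & alpha > 0)
    lo <- (y > 0 & alpha > 0) | (y < 0 & alpha < C)
    (max(yg[up]) + min(yg[lo])) / 2
  }
  obj <- sum(q * alpha) - 0.5 * sum(alpha * y * (K %*% (alpha * y)))
  list(alpha = alpha, b = b, objective = obj, iterations = iter,
       converged = converged)
}

#' Solve the soft-margin SVM dual on a precomputed kernel matrix
#'
#' Low-level interface to the package's SMO solver.  `linear_coef` allows
#' the generalized linear term used by the constrained SVM; the default of
#' all ones gives the vanilla SVM dual.
#'
#' @param K `n x n` kernel (Gram) matrix.
#' @param y Labels in `{-1, +1}`.
#' @param C Box constraint (misclassification cost).
#' @param linear_coef Length-`n` coefficients of the dual's linear term.
#' @param tol KKT violation tolerance (default `1e-8`).
#' @param max_iter Iteration cap (default `max(20000, 200 n)`).
#' @return List with `alpha`, `b`, `objective` (the maximized dual value),
#'   `iterations`, `converged`.
#' @export
solve_svm_dual <- function(K, y, C, linear_coef = NULL, tol = 1e-8,
                           max_iter = NULL) {
  y <- as.numeric(y)
  if (length(unique(y)) != 2L || !all(y %in% c(-1, 1)))
    stop("y must contain both classes, coded -1/+1", call. = FALSE)
  if (C <= 0) stop("C must be positive", call. = FALSE)
  smo_solve(K, y, C, q = linear_coef, tol = tol, max_iter = max_iter)
}

#' Fit a soft-margin kernel SVM
#'
#' Trains a two-class SVM by solving the dual quadratic program with the
#' package's SMO solver.  The decision function is the kernel expansion
#' \eqn{f(s) = \sum_j \alpha_j y_j K(s_j, s) + b}; its sign is the class.
#'
#' @param x Numeric matrix of training points (rows = instances).
#' @param y Labels; a factor, 0/1 or -1/+1 vector (coerced to -1/+1).
#' @param C Box constraint (default 10000).
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param kernel_scale RBF bandwidth \eqn{\sigma}; default is the median
#'   heuristic (median pairwise Euclidean distance of `x`).
#' @param tol,max_iter Passed to [solve_svm_dual()].
#' @return Object of class `kernel_svm`: support points, dual coefficients,
#'   bias, kernel settings and the dual objective.
#' @examples
#' x <- matrix(c(-1, 1), 2, 1)
#' fit <- kernel_svm(x, c(-1, 1), C = 10, kernel = "linear")
#' fit$alpha  # c(0.5, 0.5)
#' @export
kernel_svm <- function(x, y, C = 10000, kernel = c("rbf", "linear"),
                       kernel_scale = NULL, tol = 1e-8, max_iter = NULL) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- svm_labels(y)
  if (nrow(x) < 2L) stop("need at least two training points", call. = FALSE)
  if (is.null(kernel_scale)) kernel_scale <- median_heuristic(x)
  K <- svm_kernel(x, x, kernel, kernel_scale)
  sol <- solve_svm_dual(K, y, C, tol = tol, max_iter = max_iter)
  sv_tol <- 1e-8 * C
  sv <- which(sol$alpha > sv_tol)
  structure(list(
    alpha = sol$alpha, b = sol$b, y = y, x = x,
    sv_index = sv, support_points = x[sv, , drop = FALSE],
    sv_alpha = sol$alpha[sv], sv_y = y[sv],
    cost = C, kernel = kernel, kernel_scale = kernel_scale,
    objective = sol$objective, iterations = sol$iterations,
    converged = sol$converged
  ), class = "kernel_svm")
}

## coerce labels to -1/+1
svm_labels <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  u <- sort(unique(y))
  if (length(u) != 2L) stop("y must contain exactly two classes", call. = FALSE)
  if (identical(u, c(0, 1))) y <- 2 * y - 1
  if (!all(y %in% c(-1, 1)))
    stop("labels must be coded 0/1 or -1/+1", call. = FALSE)
  y
}

median_heuristic <- function(x) {
  n <- nrow(x)
  ## deterministic thinning keeps the heuristic reproducible without
  ## touching the RNG stream
  idx <- if (n > 200) unique(round(seq(1, n, length.out = 200))) else seq_len(n)
  d <- stats::dist(x[idx, , drop = FALSE])
  m <- stats::median(d)
  if (!is.finite(m) || m <= 0) 1 else m
}

#' @export
print.kernel_svm <- function(x, ...) {
  cat(sprintf("kernel SVM (%s kernel): %d training points, %d support vectors\n",
              x$kernel, length(x$y), length(x$sv_index)))
  cat(sprintf("  C = %g, kernel scale = %.4g, bias = %.4g, dual objective = %.6g\n",
              x$cost, x$kernel_scale, x$b, x$objective))
  invisible(x)
}

#' @export
coef.kernel_svm <- function(object, ...) object$alpha

#' Decision scores and classes for a kernel SVM
#'
#' @param object A [kernel_svm()] or [constrained_svm()] fit.
#' @param newdata Matrix of points to score.
#' @param type `"score"` (default) for the real-valued decision function or
#'   `"class"` for its sign.
#' @param ... Unused.
#' @return Numeric scores or -1/+1 classes.
#' @export
predict.kernel_svm <- function(object, newdata, type = c("score", "class"),
                               ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop("newdata has wrong dimensionality", call. = FALSE)
  s <- svm_expansion(object, newdata) + object$b
  if (type == "class") sign(s) else s
}

## kernel-expansion part sum_j alpha_j y_j K(s_j, s) over support vectors
svm_expansion <- function(object, newdata) {
  if (!length(object$sv_index)) return(rep(0, nrow(newdata)))
  Kx <- svm_kernel(newdata, object$support_points, object$kernel,
                   object$kernel_scale)
  as.vector(Kx %*% (object$sv_alpha * object$sv_y))
}

#' Decision function of a fitted classifier
#'
#' Thin wrapper around `predict(..., type = "score")` mirroring the common
#' name for the real-valued margin of an SVM.
#'
#' @inheritParams predict.kernel_svm
#' @param model A fitted classifier.
#' @return Numeric vector of decision scores.
#' @export
decision_function <- function(model, newdata) {
  stats::predict(model, newdata, type = "score")
}

#' Choose the RBF kernel scale by cross-validated AUC
#'
#' Grid search over candidate bandwidths, scoring each by mean AUC of the
#' vanilla SVM over stratified folds; ties broken by the smaller scale.
#'
#' @param x,y Training data and labels.
#' @param C Box constraint used during tuning.
#' @param grid Candidate kernel scales (default: median heuristic times
#'   `c(1/4, 1/2, 1, 2, 4)`).
#' @param n_folds Number of stratified folds (default 5).
#' @param seed Integer seed controlling the fold assignment.
#' @param tol,max_iter Passed to the solver.
#' @return The selected kernel scale (scalar).
#' @export
tune_kernel_scale <- function(x, y, C = 10000, grid = NULL, n_folds = 5,
                              seed = 1, tol = 1e-6, max_iter = NULL) {
  x <- as.matrix(x); y <- svm_labels(y)
  if (is.null(grid)) grid <- median_heuristic(x) * c(1 / 4, 1 / 2, 1, 2, 4)
  if (!length(grid)) stop("grid must be nonempty", call. = FALSE)
  grid <- sort(grid)
  if (length(grid) == 1L) return(grid)
  folds <- with_seed(derive_seed(seed, "tune-folds"),
                     stratified_folds(y, n_folds))
  mean_auc <- vapply(grid, function(ks) {
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f; te <- !tr
      if (length(unique(y[tr])) < 2L || length(unique(y[te])) < 2L)
        return(NA_real_)
      fit <- kernel_svm(x[tr, , drop = FALSE], y[tr], C = C,
                        kernel_scale = ks, tol = tol, max_iter = max_iter)
      roc_auc(stats::predict(fit, x[te, , drop = FALSE]), y[te])$auc
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  grid[which.max(mean_auc)]   # which.max takes the first (smallest) on ties
}

## stratified fold labels; retries once if a fold loses a class
stratified_folds <- function(y, n_folds) {
  for (attempt in 1:2) {
    f <- numeric(length(y))
    for (cls in unique(y)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
    }
    ok <- all(vapply(seq_len(n_folds),
                     function(k) length(unique(y[f == k])) == 2L, logical(1)))
    if (ok) return(f)
  }
  stop("could not build folds containing both classes", call. = FALSE)
}
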