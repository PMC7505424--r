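## ---------------------------------------------------------------------------
## Constrained SVM: propagates imputation uncertainty into classification.
##
## p complete datasets are sampled from the per-cell imputation
## distributions and a vanilla SVM w_i is trained on each.  A final
## classifier is then trained on one further fresh completion by solving a
## dual QP whose linear term is modified by the pre-trained ensemble:
##
##   max_alpha sum_j alpha_j - 1/2 sum_jk alpha_j alpha_k y_j y_k K(s_j,s_k)
##             + lambda sum_j alpha_j y_j W(s_j)
##   s.t. 0 <= alpha_j <= C,  sum_j alpha_j y_j = 0,
##
## where W(s) = sum_i w_i' phi(s) is evaluated through the ensemble members'
## kernel expansions.  This dual is the KKT dual of the primal
##   min 1/2 w'w + lambda sum_i w'w_i + C sum_j xi_j
## (a penalty on similarity with the pre-trained weight vectors), whose
## stationarity condition gives w = sum_j alpha_j y_j phi(s_j) - lambda
## sum_i w_i.  Two decision rules are provided: the default scores with the
## penalized expansion sum_j alpha_j y_j K(s_j, s) + b alone (the penalty
## acts through the selection of the alphas), while "full" also subtracts
## lambda W(s) as the stationarity condition implies; with many ensemble
## members the subtracted term dominates and degrades discrimination, which
## is why it is not the default.
## ---------------------------------------------------------------------------

#' Train an ensemble of SVMs on sampled completions
#'
#' Fits one vanilla SVM per completed dataset (same labels, same kernel
#' settings), preserving order.
#'
#' @param completions List of complete numeric matrices, e.g. from
#'   [sample_completions()].
#' @param y Labels (coerced to -1/+1).
#' @param C Box constraint.
#' @param kernel_scale RBF bandwidth shared by all members.
#' @param kernel `"rbf"` or `"linear"`.
#' @param tol,max_iter Passed to the solver.
#' @return List of [kernel_svm()] fits.
#' @export
train_ensemble <- function(completions, y, C = 10000, kernel_scale = NULL,
                           kernel = "rbf", tol = 1e-8, max_iter = NULL) {
  stopifnot(is.list(completions), length(completions) >= 1)
  if (is.null(kernel_scale) && kernel == "rbf")
    kernel_scale <- median_heuristic(as.matrix(completions[[1]]))
  lapply(seq_along(completions), function(i) {
    tryCatch(
      kernel_svm(completions[[i]], y, C = C, kernel = kernel,
                 kernel_scale = kernel_scale, tol = tol, max_iter = max_iter),
      error = function(e) stop("ensemble member ", i, ": ",
                               conditionMessage(e), call. = FALSE))
  })
}

## W(s) = sum_i w_i' phi(s), evaluated via each member's kernel expansion
## (bias terms are not part of the weight vectors and are excluded).
ensemble_weight_function <- function(ensemble, newdata) {
  newdata <- as.matrix(newdata)
  out <- rep(0, nrow(newdata))
  for (mdl in ensemble) out <- out + svm_expansion(mdl, newdata)
  out
}

#' Solve the ensemble-penalized SVM dual
#'
#' Trains the final constrained classifier on `S_new` given a pre-trained
#' ensemble: the dual's linear term becomes
#' \eqn{1 + \lambda y_j W(s_j)} with `W` the summed ensemble weight
#' functions.  With `lambda = 0` the solution equals the vanilla SVM on
#' `(S_new, y)`.
#'
#' @param S_new Numeric matrix: the fresh completion to train on.
#' @param y Labels (coerced to -1/+1).
#' @param ensemble Nonempty list of [kernel_svm()] fits sharing the same
#'   kernel and kernel scale.
#' @param lambda Penalty coefficient (`>= 0`, default 1).
#' @param C Box constraint (default 10000).
#' @param kernel_scale,kernel Kernel settings; must match the ensemble.
#' @param tol,max_iter Passed to the solver.
#' @return Object of class `constrained_svm` (inherits `kernel_svm`) with
#'   the additional fields `lambda`, `ensemble`, `ensemble_size` and the
#'   training-point penalty values `W_train`.
#' @export
solve_csvm_dual <- function(S_new, y, ensemble, lambda = 1, C = 10000,
                            kernel_scale = NULL, kernel = "rbf",
                            tol = 1e-8, max_iter = NULL) {
  stopifnot(is.list(ensemble), length(ensemble) >= 1)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  S_new <- as.matrix(S_new)
  y <- svm_labels(y)
  ks <- unique(vapply(ensemble, function(m) m$kernel_scale, numeric(1)))
  kn <- unique(vapply(ensemble, function(m) m$kernel, character(1)))
  if (length(ks) != 1L || length(kn) != 1L)
    stop("ensemble members disagree on kernel settings", call. = FALSE)
  if (is.null(kernel_scale)) kernel_scale <- ks
  if (kn != kernel || abs(ks - kernel_scale) > 1e-12 * max(1, ks))
    stop("kernel settings do not match the ensemble", call. = FALSE)
  W <- ensemble_weight_function(ensemble, S_new)
  K <- svm_kernel(S_new, S_new, kernel, kernel_scale)
  sol <- solve_svm_dual(K, y, C, linear_coef = 1 + lambda * y * W,
                        tol = tol, max_iter = max_iter)
  ## sol$b is the KKT bias of the full rule f(s) = sum alpha y K - lambda W + b
  ## (the lambda term is inside the linear coefficients).  For the
  ## expansion-only rule the intercept is recalibrated on the free support
  ## vectors against their +/-1 targets.
  sv_tol <- 1e-8 * C
  sv <- which(sol$alpha > sv_tol)
  free <- sol$alpha > sv_tol & sol$alpha < C - sv_tol
  expansion <- as.vector(K %*% (sol$alpha * y))
  b_exp <- if (any(free)) mean(y[free] - expansion[free]) else sol$b
  structure(list(
    alpha = sol$alpha, b = sol$b, y = y, x = S_new,
    sv_index = sv, support_points = S_new[sv, , drop = FALSE],
    sv_alpha = sol$alpha[sv], sv_y = y[sv],
    cost = C, kernel = kernel, kernel_scale = kernel_scale,
    objective = sol$objective, iterations = sol$iterations,
    converged = sol$converged,
    lambda = lambda, ensemble = ensemble,
    ensemble_size = length(ensemble), W_train = W, b_expansion = b_exp
  ), class = c("constrained_svm", "kernel_svm"))
}

#' Fit the constrained SVM from an uncertain imputation
#'
#' End-to-end wrapper: samples `p` completions from the imputation
#' distributions, trains the SVM ensemble, draws one further fresh
#' completion, and solves the ensemble-penalized dual on it.
#'
#' @param imp An [imputed_data()] object (e.g. from [predict.gplvm()]).
#' @param y Labels (coerced to -1/+1), one per row of `imp$values`.
#' @param p Ensemble size (number of sampled completions; default 200).
#' @param lambda Penalty coefficient (default 1).
#' @param C Box constraint (default 10000).
#' @param kernel_scale RBF bandwidth; default median heuristic on the
#'   imputation means.
#' @param kernel `"rbf"` (default) or `"linear"`.
#' @param seed Integer seed for the completion draws.
#' @param rows Optional row subset (e.g. a down-sampled index set) used for
#'   training; completions are drawn for all rows first so that the subset
#'   shares the observed entries.
#' @param tol,max_iter Passed to the solver.
#' @return A `constrained_svm` fit (see [solve_csvm_dual()]).
#' @export
constrained_svm <- function(imp, y, p = 200, lambda = 1, C = 10000,
                            kernel_scale = NULL, kernel = "rbf", seed = 1,
                            rows = NULL, tol = 1e-8, max_iter = NULL) {
  stopifnot(inherits(imp, "imputed_data"))
  y <- svm_labels(y)
  if (length(y) != nrow(imp$values))
    stop("length(y) must equal nrow(imp$values)", call. = FALSE)
  if (is.null(rows)) rows <- seq_len(nrow(imp$values))
  if (is.null(kernel_scale) && kernel == "rbf")
    kernel_scale <- median_heuristic(imp$values[rows, , drop = FALSE])
  comps <- sample_completions(imp, p + 1L, seed = derive_seed(seed, "csvm-samples"))
  comps <- lapply(comps, function(m) m[rows, , drop = FALSE])
  ens <- train_ensemble(comps[seq_len(p)], y[rows], C = C,
                        kernel_scale = kernel_scale, kernel = kernel,
                        tol = tol, max_iter = max_iter)
  solve_csvm_dual(comps[[p + 1L]], y[rows], ens, lambda = lambda, C = C,
                  kernel_scale = kernel_scale, kernel = kernel,
                  tol = tol, max_iter = max_iter)
}

#' @export
print.constrained_svm <- function(x, ...) {
  cat(sprintf("constrained SVM: %d training points, %d support vectors\n",
              length(x$y), length(x$sv_index)))
  cat(sprintf("  lambda = %g, ensemble size p = %d, C = %g, kernel scale = %.4g\n",
              x$lambda, x$ensemble_size, x$cost, x$kernel_scale))
  cat(sprintf("  bias = %.4g, dual objective = %.6g\n", x$b, x$objective))
  invisible(x)
}

#' @rdname predict.kernel_svm
#' @param decision_rule `"expansion-only"` (default) scores with the
#'   penalized solution's own kernel expansion,
#'   \eqn{\sum_j \alpha_j y_j K(s_j, s) + b}; `"full"` additionally
#'   subtracts \eqn{\lambda W(s)}, the term implied by the stationarity
#'   condition of the penalized primal.  The default classifies with the
#'   support vectors the penalty selected, which is the variant that
#'   improves on the vanilla SVM under imputation uncertainty; `"full"` is
#'   retained for ablation.
#' @export
predict.constrained_svm <- function(object, newdata,
                                    type = c("score", "class"),
                                    decision_rule = c("expansion-only", "full"),
                                    ...) {
  type <- match.arg(type)
  decision_rule <- match.arg(decision_rule)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != ncol(object$x))
    stop("newdata has wrong dimensionality", call. = FALSE)
  s <- svm_expansion(object, newdata)
  if (decision_rule == "full" && object$lambda > 0)
    s <- s - object$lambda * ensemble_weight_function(object$ensemble, newdata) +
      object$b
  else
    s <- s + object$b_expansion
  if (type == "class") sign(s) else s
}
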