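#' Imputed dataset: per-cell mean and uncertainty
#'
#' Result container shared by all imputers.  Observed cells are copied
#' verbatim; each missing cell (i, j) carries an imputation mean
#' \eqn{\pi_{ij}} in `values` and a standard deviation \eqn{\sigma_{ij}} in
#' `sd` (zero for observed cells, and identically zero for deterministic
#' imputers such as mean imputation and LOCF).
#'
#' @param values Numeric matrix with missing cells replaced by imputation
#'   means.
#' @param sd Numeric matrix of per-cell imputation standard deviations
#'   (`>= 0`; positive exactly on masked cells for probabilistic imputers).
#' @param mask Logical matrix, `TRUE` = cell was missing.
#' @param train_stats Optional list with per-column `mean` and `sd` used for
#'   standardization (as stored by [gplvm()]); needed by
#'   [imputation_mae()] when reporting errors in standardized units.
#' @param method Character label of the imputer.
#' @return An object of class `imputed_data` with components `values`, `sd`,
#'   `mask`, `n_miss`, `miss_index` (two-column matrix of missing positions),
#'   `train_stats`, `method`.
#' @export
imputed_data <- function(values, sd, mask, train_stats = NULL,
                         method = "unknown") {
  stopifnot(is.matrix(values), identical(dim(values), dim(sd)),
            identical(dim(values), dim(mask)), is.logical(mask))
  if (anyNA(values)) stop("imputed values must be complete", call. = FALSE)
  if (any(sd < 0)) stop("imputation sd must be non-negative", call. = FALSE)
  if (any(sd[!mask] != 0))
    stop("observed cells must have sd 0", call. = FALSE)
  structure(list(values = values, sd = sd, mask = mask,
                 n_miss = sum(mask),
                 miss_index = which(mask, arr.ind = TRUE),
                 train_stats = train_stats, method = method),
            class = "imputed_data")
}

#' @export
print.imputed_data <- function(x, ...) {
  cat(sprintf("imputed_data (%s): %d x %d, %d imputed cells", x$method,
              nrow(x$values), ncol(x$values), x$n_miss))
  if (x$n_miss > 0 && any(x$sd > 0))
    cat(sprintf(", median imputation sd %.3f", stats::median(x$sd[x$mask])))
  cat("\n")
  invisible(x)
}

#' Sample complete datasets from an imputation's uncertainty
#'
#' Draws `p` complete versions of the data: observed entries are identical
#' across all draws, and every missing entry (i, j) is sampled independently
#' from \eqn{N(\pi_{ij}, \sigma_{ij}^2)}.  This is the sampling step feeding
#' the ensemble of classifiers inside [constrained_svm()].
#'
#' @param imp An [imputed_data()] object.
#' @param p Number of completions to draw.
#' @param seed Integer seed; draws are reproducible given `seed`.
#' @return A list of `p` numeric matrices.
#' @export
sample_completions <- function(imp, p, seed = 1) {
  stopifnot(inherits(imp, "imputed_data"), p >= 1)
  idx <- imp$mask
  with_seed(seed, {
    lapply(seq_len(p), function(i) {
      out <- imp$values
      if (any(idx))
        out[idx] <- stats::rnorm(sum(idx), mean = imp$values[idx],
                                 sd = imp$sd[idx])
      out
    })
  })
}
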