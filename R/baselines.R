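#' Column-mean imputation
#'
#' Replaces every missing cell with the training mean of its column.  The
#' imputation standard deviation is identically zero: this baseline carries
#' no uncertainty information.
#'
#' @param data A [masked_matrix()].
#' @param train_stats Optional list with a per-column `mean` vector (as
#'   stored by [gplvm()] or [standardize_split()]); defaults to the means of
#'   the observed cells of `data` itself.
#' @return An [imputed_data()] with `sd = 0` everywhere.
#' @export
mean_impute <- function(data, train_stats = NULL) {
  stopifnot(inherits(data, "masked_matrix"))
  vals <- data$values; mask <- data$mask
  if (is.null(train_stats)) {
    mu <- colMeans(vals, na.rm = TRUE)
    if (anyNA(mu))
      stop("column(s) entirely missing: ",
           paste(data$column_names[is.na(mu)], collapse = ", "), call. = FALSE)
    train_stats <- list(mean = mu, sd = rep(1, ncol(vals)),
                        columns = data$column_names)
  } else {
    mu <- train_stats$mean
    if (anyNA(mu))
      stop("training mean unavailable for column(s): ",
           paste(names(mu)[is.na(mu)], collapse = ", "), call. = FALSE)
  }
  out <- vals
  out[mask] <- rep(mu, each = nrow(vals))[mask]
  imputed_data(out, matrix(0, nrow(vals), ncol(vals)), mask,
               train_stats = train_stats, method = "mean")
}

#' Last-observation-carried-forward imputation
#'
#' Fills each missing cell with the most recent preceding observed value in
#' the same column, rows ordered by `order_key` (ties broken by row index).
#' Cells with no preceding observation fall back to the column mean.  On a
#' cross-sectional table this requires an explicit row ordering (e.g.
#' admission order); the choice of ordering is the user's.
#'
#' @param data A [masked_matrix()].
#' @param order_key Numeric vector, one value per row, defining the
#'   carry-forward order.  Defaults to the row order of `data`.
#' @param train_stats As in [mean_impute()]; used for the fallback mean.
#' @return An [imputed_data()] with `sd = 0` everywhere.
#' @export
locf_impute <- function(data, order_key = NULL, train_stats = NULL) {
  stopifnot(inherits(data, "masked_matrix"))
  n <- nrow(data$values)
  if (is.null(order_key)) order_key <- seq_len(n)
  if (length(order_key) != n || anyNA(order_key))
    stop("'order_key' must be a complete vector with one value per row",
         call. = FALSE)
  ord <- order(order_key, seq_len(n))
  vals <- data$values; mask <- data$mask
  mu <- if (is.null(train_stats)) colMeans(vals, na.rm = TRUE) else
    train_stats$mean
  out <- vals
  for (j in seq_len(ncol(vals))) {
    col <- vals[ord, j]
    filled <- col
    last <- NA_real_
    for (i in seq_along(col)) {
      if (is.na(filled[i])) filled[i] <- last else last <- filled[i]
    }
    filled[is.na(filled)] <- mu[j]   # leading missing: column-mean fallback
    out[ord, j] <- filled
  }
  imputed_data(out, matrix(0, nrow(vals), ncol(vals)), mask,
               train_stats = train_stats, method = "locf")
}
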