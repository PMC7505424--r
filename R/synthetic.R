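#' Configuration for the synthetic cohort generator
#'
#' Describes a synthetic dataset with the structure of a clinical feature
#' table: `n_features` correlated continuous columns driven by a
#' `latent_dim`-dimensional latent state plus Gaussian noise, binary labels
#' linked to the latent state through a logistic model, and
#' missing-at-random missingness induced by a regression-quartile rule (see
#' [induce_missingness()]).
#'
#' @param n_instances Number of rows (default 1000).
#' @param n_features Number of feature columns (default 15).
#' @param latent_dim True latent dimensionality (default 3; must be smaller
#'   than `n_features`).
#' @param noise_var Observation-noise variance added to the mixed latent
#'   signal, relative to unit signal scale (default 0.1).
#' @param feature_map `"linear"` (random linear mixing, default) or
#'   `"gp-sample"` (each feature drawn from a GP over the latents with a
#'   squared-exponential kernel, giving nonlinear dependence).
#' @param beta Label-model coefficients on the latent state (default all 1).
#' @param pos_rate Target positive rate; the logistic intercept is solved so
#'   the expected rate matches (default 0.118, a typical 30-day readmission
#'   rate in heart-failure cohorts).
#' @param missing_fraction Proportion of instances selected to contain
#'   missing values (default 0.2; the companion regime is 0.3).
#' @param quartile_window Pair of probabilities (or labels `"min"`, `"q1"`,
#'   `"q2"`, `"q3"`, `"max"`) bounding the fitted-value window inside which
#'   a cell is set missing; default `c("q2", "q3")`, i.e. between the median
#'   and the 75th percentile.
#' @param mar_rule `"fitted"` (default) masks a cell when its *fitted* value
#'   lies in the window; `"observed"` compares the observed value instead.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_instances = 1000, n_features = 15, latent_dim = 3,
                       noise_var = 0.1, feature_map = c("linear", "gp-sample"),
                       beta = NULL, pos_rate = 0.118,
                       missing_fraction = 0.2,
                       quartile_window = c("q2", "q3"),
                       mar_rule = c("fitted", "observed"), seed = 1) {
  feature_map <- match.arg(feature_map)
  mar_rule <- match.arg(mar_rule)
  if (latent_dim >= n_features)
    stop("latent_dim must be smaller than n_features", call. = FALSE)
  if (missing_fraction < 0 || missing_fraction > 1)
    stop("missing_fraction must be in [0, 1]", call. = FALSE)
  if (pos_rate <= 0 || pos_rate >= 1)
    stop("pos_rate must be in (0, 1)", call. = FALSE)
  if (is.null(beta)) beta <- rep(1, latent_dim)
  stopifnot(length(beta) == latent_dim)
  qw <- parse_quartile_window(quartile_window)
  structure(list(n_instances = as.integer(n_instances),
                 n_features = as.integer(n_features),
                 latent_dim = as.integer(latent_dim),
                 noise_var = noise_var, feature_map = feature_map,
                 beta = beta, pos_rate = pos_rate,
                 missing_fraction = missing_fraction,
                 quartile_window = qw, mar_rule = mar_rule,
                 seed = as.integer(seed)),
            class = "sim_config")
}

parse_quartile_window <- function(w) {
  lab <- c(min = 0, q1 = 0.25, q2 = 0.5, q3 = 0.75, max = 1)
  if (is.character(w)) {
    w <- tolower(w)
    if (!all(w %in% names(lab)))
      stop("quartile labels must be among min, q1, q2, q3, max", call. = FALSE)
    w <- unname(lab[w])
  }
  w <- as.numeric(w)
  if (length(w) != 2L || any(w < 0 | w > 1) || w[1] >= w[2])
    stop("quartile_window must be two increasing probabilities in [0, 1]",
         call. = FALSE)
  w
}

#' Generate a complete synthetic cohort
#'
#' Draws latent states from a standard normal, maps them to features
#' (linear mixing or GP sample), adds Gaussian noise, standardizes each
#' column, and draws binary labels from a logistic model on the latent
#' state whose intercept is solved to hit the configured positive rate.
#'
#' @param config A [sim_config()].
#' @return List with `data` (a complete [masked_matrix()]), `labels`
#'   (0/1 vector), `latent` (the true latent states) and `prob` (the
#'   label-model probabilities).
#' @export
generate_complete <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  N <- config$n_instances; M <- config$n_features; Q <- config$latent_dim
  with_seed(derive_seed(config$seed, "generate"), {
    X <- matrix(stats::rnorm(N * Q), N, Q)
    F0 <- switch(config$feature_map,
      linear = X %*% matrix(stats::rnorm(Q * M), Q, M),
      `gp-sample` = gp_sample_features(X, M))
    F0 <- scale(F0)                      # unit signal scale per column
    Y <- F0 + matrix(stats::rnorm(N * M, sd = sqrt(config$noise_var)), N, M)
    Y <- scale(Y)
    attr(Y, "scaled:center") <- attr(Y, "scaled:scale") <- NULL
    colnames(Y) <- sprintf("f%02d", seq_len(M))
    eta <- as.vector(X %*% config$beta)
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) -
                           config$pos_rate, c(-50, 50))$root
    prob <- stats::plogis(b0 + eta)
    labels <- stats::rbinom(N, 1, prob)
    list(data = masked_matrix(Y), labels = labels, latent = X, prob = prob)
  })
}

## one exact GP draw per feature over the latent inputs (squared-exponential
## kernel, unit variance, lengthscale 1); cost O(N^3), intended for the
## moderate N of simulation studies
gp_sample_features <- function(X, M) {
  K <- rbf_kernel(X, X, variance = 1, lengthscales = 1)
  L <- chol_jitter(K, 1e-8)
  crossprod(L, matrix(stats::rnorm(nrow(X) * M), nrow(X), M))
}

#' Induce missingness by the regression-quartile rule
#'
#' Three steps: (1) for each feature, fit a linear regression on all
#' remaining features over the complete data and compute the quantiles of
#' its fitted values; (2) randomly select `floor(missing_fraction * N)`
#' instances; (3) within each selected instance, set feature j missing iff
#' its fitted value (or, with `rule = "observed"`, its observed value) lies
#' inside the configured quantile window of feature j's fitted values.
#' Because the rule depends on the other features only (through the fitted
#' value), the mechanism is missing at random.
#'
#' @param Y Complete numeric matrix or [masked_matrix()] with empty mask.
#' @param missing_fraction Proportion of instances selected, in (0, 1)
#'   (0 returns an empty mask).
#' @param quartile_window As in [sim_config()].
#' @param seed Integer seed for the instance selection.
#' @param rule `"fitted"` or `"observed"`; see [sim_config()].
#' @return A [masked_matrix()] with attributes `selected` (the chosen row
#'   indices), `window`, and `rule`.
#' @export
induce_missingness <- function(Y, missing_fraction = 0.2,
                               quartile_window = c("q2", "q3"), seed = 1,
                               rule = c("fitted", "observed")) {
  rule <- match.arg(rule)
  if (inherits(Y, "masked_matrix")) {
    stopifnot(n_missing(Y) == 0L)
    Y <- Y$values
  }
  Y <- as.matrix(Y)
  if (missing_fraction < 0 || missing_fraction >= 1)
    stop("missing_fraction must be in [0, 1)", call. = FALSE)
  qw <- parse_quartile_window(quartile_window)
  N <- nrow(Y); M <- ncol(Y)
  mask <- matrix(FALSE, N, M)
  n_sel <- floor(missing_fraction * N)
  sel <- if (n_sel > 0)
    sort(with_seed(derive_seed(seed, "select"), sample.int(N, n_sel)))
  else integer(0)
  if (length(sel)) {
    for (j in seq_len(M)) {
      fitj <- stats::lm.fit(cbind(1, Y[, -j, drop = FALSE]), Y[, j])$fitted.values
      bounds <- stats::quantile(fitj, qw, names = FALSE, type = 7)
      ref <- if (rule == "fitted") fitj else Y[, j]
      mask[sel, j] <- ref[sel] >= bounds[1] & ref[sel] <= bounds[2]
    }
  }
  out <- masked_matrix(Y, mask)
  attr(out, "selected") <- sel
  attr(out, "window") <- qw
  attr(out, "rule") <- rule
  out
}

#' Build a complete synthetic benchmark bundle
#'
#' Generates a complete cohort, induces missingness, and packages truth,
#' masked data, labels and a manifest capturing the full configuration.
#' With `dir` set, writes `truth.csv`, `masked.csv`, `mask.csv`,
#' `labels.csv` and `manifest.json`; values round-trip bit-exactly through
#' [read_masked_csv()] (17 significant digits).
#'
#' @param config A [sim_config()] (or a manifest list previously written by
#'   this function, enabling exact replay).
#' @param dir Optional output directory.
#' @param force Overwrite an existing `dir` (default `FALSE`).
#' @return List of class `sim_benchmark`: `truth` (matrix), `data`
#'   ([masked_matrix()]), `labels`, `latent`, `manifest`.
#' @export
make_benchmark <- function(config, dir = NULL, force = FALSE) {
  if (!inherits(config, "sim_config") && is.list(config) &&
      !is.null(config$config))
    config <- do.call(sim_config, lapply(config$config, unlist))
  stopifnot(inherits(config, "sim_config"))
  comp <- generate_complete(config)
  masked <- induce_missingness(comp$data, config$missing_fraction,
                               config$quartile_window,
                               seed = derive_seed(config$seed, "missing"),
                               rule = config$mar_rule)
  manifest <- list(config = unclass(config),
                   generator = "missgp::make_benchmark", format = 1L)
  bundle <- structure(list(truth = comp$data$values, data = masked,
                           labels = comp$labels, latent = comp$latent,
                           manifest = manifest),
                      class = "sim_benchmark")
  if (!is.null(dir)) {
    if (dir.exists(dir) && length(list.files(dir)) && !force)
      stop("output dir exists and is nonempty; use force = TRUE", call. = FALSE)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_matrix_csv(bundle$truth, file.path(dir, "truth.csv"))
    write_matrix_csv(masked$values, file.path(dir, "masked.csv"))
    utils::write.csv(as.data.frame(masked$mask * 1L),
                     file.path(dir, "mask.csv"), row.names = FALSE)
    utils::write.csv(data.frame(label = bundle$labels),
                     file.path(dir, "labels.csv"), row.names = FALSE)
    jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bundle
}

## full-precision CSV writer (17 significant digits round-trip doubles)
write_matrix_csv <- function(m, file) {
  df <- as.data.frame(m)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste(colnames(df), collapse = ","), con)
  body <- apply(m, 1, function(r)
    paste(ifelse(is.na(r), "NA", sprintf("%.17g", r)), collapse = ","))
  writeLines(body, con)
  invisible(file)
}

#' @export
print.sim_benchmark <- function(x, ...) {
  cat("synthetic benchmark bundle\n")
  print(x$data)
  cat(sprintf("  positives: %d / %d (%.1f%%)\n", sum(x$labels),
              length(x$labels), 100 * mean(x$labels)))
  invisible(x)
}
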