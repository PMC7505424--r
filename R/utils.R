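## Internal numerical helpers shared across the package.

#' @keywords internal
"_PACKAGE"

## Cholesky with escalating diagonal jitter.  Kernel Gram matrices are
## positive semidefinite in exact arithmetic but can lose definiteness in
## floating point; a small diagonal inflation restores it.  Starts at
## `jitter` and escalates tenfold up to `max_jitter` before failing.
chol_jitter <- function(A, jitter = 1e-6, max_jitter = 1e-3) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A))
  d <- nrow(A)
  j <- jitter
  repeat {
    L <- tryCatch(chol(A + diag(j, d)), error = function(e) NULL)
    if (!is.null(L)) {
      attr(L, "jitter") <- j
      return(L)
    }
    if (j >= max_jitter) {
      stop("Cholesky factorization failed even with diagonal jitter ",
           max_jitter, "; the kernel matrix is severely ill-conditioned. ",
           "Consider fewer inducing points or larger lengthscales.",
           call. = FALSE)
    }
    j <- j * 10
  }
}

## Derive a reproducible child seed from a parent seed and a stage label.
## Keeps results independent across stages while fully determined by the
## single user-facing seed.  Result always fits in a 32-bit signed integer.
derive_seed <- function(seed, label) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(as.character(label)) * seq_along(utf8ToInt(as.character(label))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647L)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## log(det(A)) from an upper-triangular Cholesky factor.
logdet_from_chol <- function(L) 2 * sum(log(diag(L)))

`%||%` <- function(a, b) if (is.null(a)) b else a
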