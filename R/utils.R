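#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded at `seed` and restores the caller's
#' RNG state afterwards, so seeded package functions never perturb user code.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

# Derive a sub-stream seed from a master seed and a stage offset, kept within
# 32-bit integer range. Per-stage streams use fixed offsets so each stage is
# reproducible in isolation.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Restrict an object to a set of samples
#'
#' @param x a `geno_matrix` or `trait_matrix`.
#' @param samples character vector of sample IDs to keep (order preserved).
#' @return object of the same class restricted to those samples.
#' @export
subset_samples <- function(x, samples) UseMethod("subset_samples")

#' @export
subset_samples.geno_matrix <- function(x, samples) {
  stopifnot(all(samples %in% rownames(x$dosages)))
  x$dosages <- x$dosages[samples, , drop = FALSE]
  if (!is.null(x$truth_dosages))
    x$truth_dosages <- x$truth_dosages[samples, , drop = FALSE]
  if (!is.null(x$covariates))
    x$covariates <- x$covariates[match(samples, x$covariates$sample), , drop = FALSE]
  x
}

#' @export
subset_samples.trait_matrix <- function(x, samples) {
  stopifnot(all(samples %in% rownames(x$values)))
  x$values <- x$values[samples, , drop = FALSE]
  x$detection <- x$detection[samples, , drop = FALSE]
  x
}

# Squared Pearson correlation, NA if undefined.
r2_of <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  if (sum(ok) < 3L) return(NA_real_)
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)^2
}
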