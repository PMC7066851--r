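#' Z-score the rows of a matrix
#'
#' Centers and scales each row (gene) across columns (samples) using the
#' sample standard deviation (n - 1 denominator).
#'
#' @param x Numeric matrix (genes x samples).
#' @param drop_constant Drop zero-variance rows (with a warning) instead of
#'   erroring.
#' @return Matrix of the same shape (minus dropped rows).
#' @keywords internal
zscore_rows <- function(x, drop_constant = FALSE) {
  stopifnot(is.matrix(x), is.numeric(x))
  mu <- rowMeans(x)
  sdev <- apply(x, 1L, stats::sd)
  zero <- sdev == 0 | !is.finite(sdev)
  if (any(zero)) {
    if (!drop_constant) {
      stop("zero-variance gene(s): ",
           paste(utils::head(rownames(x)[zero], 5L), collapse = ", "))
    }
    warning("dropping ", sum(zero), " zero-variance gene(s)")
    x <- x[!zero, , drop = FALSE]
    mu <- mu[!zero]
    sdev <- sdev[!zero]
  }
  (x - mu) / sdev
}

#' Derive independent per-layer seeds from a master seed
#'
#' @param seed Master integer seed.
#' @param n Number of layer seeds.
#' @return Integer vector of length `n`, each below 2^31.
#' @keywords internal
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement (via [mclust::adjustedRandIndex()]); the
#' recovery metric for comparing inferred clusters with latent truth labels.
#'
#' @param a,b Two label vectors of equal length.
#' @return ARI in [-1, 1]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  mclust::adjustedRandIndex(a, b)
}
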