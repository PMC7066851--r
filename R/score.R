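#' Per-sample m6A score from a phenotype-gene signature
#'
#' Each signature gene is z-scored across samples; the samples x genes
#' matrix is decomposed by SVD (PCA on the correlation scale) and the score
#' is the per-sample sum of the first two principal-component projections,
#' `m6Ascore_s = PC1_s + PC2_s`. This focuses the score on the largest block
#' of well-correlated genes while down-weighting genes that do not track
#' with other signature members. Because PC signs are arbitrary, each
#' component is oriented so its largest-|loading| gene loads positively;
#' `orient_to` optionally re-orients the final score to correlate positively
#' with a reference signature (e.g. a stromal panel), reproducing the
#' "high score = stromal / immune-excluded" reading.
#'
#' @param expr Genes x samples matrix (>= 3 samples).
#' @param signature_genes Signature gene ids (>= 2 present with nonzero
#'   variance).
#' @param orient_to Optional numeric vector (per sample, e.g. a
#'   [zscore_signature()] of a stromal panel); if the score correlates
#'   negatively with it, the score is negated.
#' @return List (class `score_result`): `score` (named per sample), `pc1`,
#'   `pc2`, `loadings` (genes x 2), `var_explained` (fractions for PC1/PC2),
#'   `genes` (used), `orientation` (the sign applied per component and any
#'   final flip).
#' @export
compute_m6ascore <- function(expr, signature_genes, orient_to = NULL) {
  if (ncol(expr) < 3L) stop("need at least 3 samples")
  present <- unique(intersect(signature_genes, rownames(expr)))
  if (length(present) < 2L) stop("fewer than 2 signature genes present")
  sub <- expr[present, , drop = FALSE]
  sdev <- apply(sub, 1L, stats::sd)
  usable <- sdev > 0
  if (sum(usable) < 2L) stop("fewer than 2 signature genes with nonzero variance")
  z <- zscore_rows(sub[usable, , drop = FALSE])
  X <- t(z)                                    # samples x genes
  sv <- svd(X)
  proj <- sv$u %*% diag(sv$d, nrow = length(sv$d))
  load <- sv$v
  signs <- c(1, 1)
  for (comp in 1:2) {
    top <- which.max(abs(load[, comp]))
    if (load[top, comp] < 0) signs[comp] <- -1
  }
  pc1 <- proj[, 1L] * signs[1L]
  pc2 <- proj[, 2L] * signs[2L]
  loadings <- cbind(PC1 = load[, 1L] * signs[1L],
                    PC2 = load[, 2L] * signs[2L])
  rownames(loadings) <- rownames(z)
  score <- pc1 + pc2
  flipped <- FALSE
  if (!is.null(orient_to)) {
    stopifnot(length(orient_to) == ncol(expr))
    if (stats::cor(score, orient_to) < 0) {
      score <- -score; pc1 <- -pc1; pc2 <- -pc2
      loadings <- -loadings
      flipped <- TRUE
    }
  }
  names(score) <- names(pc1) <- names(pc2) <- colnames(expr)
  structure(list(score = score, pc1 = pc1, pc2 = pc2, loadings = loadings,
                 var_explained = (sv$d^2 / sum(sv$d^2))[1:2],
                 genes = rownames(z),
                 orientation = list(component_signs = signs,
                                    flipped_to_reference = flipped)),
            class = "score_result")
}

#' Dichotomize a score at a cutpoint
#'
#' `low` = score <= cutpoint, `high` = score > cutpoint. The cutpoint must
#' split the cohort into two non-empty groups.
#'
#' @param score Numeric vector.
#' @param cutpoint Threshold (typically from [max_stat_cutpoint()]).
#' @return Factor with levels `low`, `high`.
#' @export
dichotomize_score <- function(score, cutpoint) {
  if (cutpoint < min(score) || cutpoint >= max(score)) {
    stop("cutpoint would create an empty group")
  }
  factor(ifelse(score <= cutpoint, "low", "high"), levels = c("low", "high"))
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-aware) with the t approximation on
#' n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors (n >= 3).
#' @return List: `rho`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need n >= 3")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) stop("zero rank variance")
  rho <- stats::cor(rx, ry)
  n <- length(x)
  p <- if (abs(rho) == 1) 0 else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Kruskal-Wallis rank test
#'
#' Tie-corrected H statistic with a chi-square reference on k - 1 degrees of
#' freedom ([stats::kruskal.test()]); identical values across the board give
#' `H = 0, p = 1` rather than an error.
#'
#' @param values Numeric vector.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List: `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  if (length(unique(values)) == 1L) {
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter), p = kt$p.value)
}

#' Wilcoxon rank-sum (Mann-Whitney U) test
#'
#' U reported for the first sample; exact p for small tie-free inputs,
#' otherwise the tie-corrected normal approximation, two-sided
#' ([stats::wilcox.test()]).
#'
#' @param x,y Non-empty numeric vectors.
#' @return List: `U`, `p`.
#' @export
wilcoxon_ranksum <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Fisher exact test on a 2x2 table
#'
#' Two-sided p by the probability-mass rule (sum of conditional
#' hypergeometric probabilities no larger than the observed table's, as in
#' [stats::fisher.test()]); the odds ratio is the sample `ad/bc` with a 0.5
#' continuity add when any cell is zero. A zero margin gives `p = 1` and an
#' undefined (NA) odds ratio.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return List: `odds_ratio`, `p`, `or_defined`.
#' @export
fisher_exact_2x2 <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2L))
  if (any(table < 0) || any(table != round(table))) {
    stop("counts must be non-negative integers")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    return(list(odds_ratio = NA_real_, p = 1, or_defined = FALSE))
  }
  a <- table[1, 1]; b <- table[1, 2]; c <- table[2, 1]; d <- table[2, 2]
  or <- if (any(table == 0)) {
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5))
  } else (a * d) / (b * c)
  p <- stats::fisher.test(table)$p.value
  list(odds_ratio = or, p = p, or_defined = TRUE)
}

#' Rank-based AUC
#'
#' `AUC = U / (n1 * n0)` with mid-rank tie handling: the probability that a
#' positive-class score exceeds a negative-class score (ties count 1/2).
#'
#' @param score Numeric vector.
#' @param labels Binary labels (1/TRUE = positive class); both classes must
#'   be present.
#' @return AUC in [0, 1].
#' @export
auc_rank <- function(score, labels) {
  pos <- as.logical(labels)
  if (anyNA(pos)) stop("labels must be binary")
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(score)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
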