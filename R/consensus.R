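#' Resampling consensus clustering of samples on a feature subset
#'
#' For each of `B` resamples, a fraction `p_item` of samples is drawn without
#' replacement and clustered by the base clusterer — agglomerative clustering
#' on 1 - Pearson correlation of the (per-gene z-scored) feature vectors with
#' average linkage, cut at `k` (`base = "kmeans"` swaps in k-means on the
#' z-scored features). The consensus matrix is the elementwise ratio of
#' co-cluster counts to co-sampling counts; final labels come from
#' agglomerative clustering (average linkage) of `1 - M` cut at `k`.
#'
#' @param expr Genes x samples matrix (log2 scale).
#' @param feature_ids Genes to cluster on (e.g. the 21 m6A regulators).
#' @param k Number of clusters, `2 <= k < n_samples`.
#' @param B Number of resampling repetitions (1000 for production runs).
#' @param p_item Sample-inclusion fraction per resample.
#' @param p_feature Feature-inclusion fraction per resample (1 = use all
#'   features every time). Subsampling features as well as samples exposes
#'   merge ambiguity at too-small k that item resampling alone can miss when
#'   the base clusterer is deterministic.
#' @param seed Integer seed for the resampling stream.
#' @param base Base clusterer, `"hclust"` (default) or `"kmeans"`.
#' @return List (class `consensus_run`): `k`, `B`, `p_item`,
#'   `consensus_matrix` (samples x samples in [0, 1], unit diagonal),
#'   `labels` (named integer vector in 1..k), `cocluster_counts`,
#'   `cosample_counts`, `seed`.
#' @export
run_consensus <- function(expr, feature_ids, k, B = 1000L, p_item = 0.8,
                          p_feature = 1.0, seed = 1L,
                          base = c("hclust", "kmeans")) {
  base <- match.arg(base)
  missing_feat <- setdiff(feature_ids, rownames(expr))
  if (length(missing_feat)) {
    stop("feature(s) absent from expression matrix: ",
         paste(utils::head(missing_feat, 5L), collapse = ", "))
  }
  n <- ncol(expr)
  if (!(k >= 2L && k < n)) stop("k must satisfy 2 <= k < n_samples")
  stopifnot(B >= 1L, p_item > 0, p_item <= 1, p_feature > 0, p_feature <= 1)
  x <- expr[feature_ids, , drop = FALSE]
  x <- zscore_rows(x)              # errors on zero-variance feature
  samp_ids <- colnames(expr)

  cluster_once <- function(xsub) {
    if (base == "kmeans") {
      stats::kmeans(t(xsub), centers = k, nstart = 5L)$cluster
    } else {
      d <- stats::as.dist(1 - stats::cor(xsub))
      stats::cutree(stats::hclust(d, method = "average"), k = k)
    }
  }

  co_cluster <- matrix(0L, n, n)
  co_sample <- matrix(0L, n, n)
  n_draw <- ceiling(p_item * n)
  nf <- nrow(x)
  nf_draw <- ceiling(p_feature * nf)
  set.seed(as.integer(seed))
  for (b in seq_len(B)) {
    idx <- if (p_item < 1) sort(sample.int(n, n_draw)) else seq_len(n)
    fidx <- if (p_feature < 1) sort(sample.int(nf, nf_draw)) else seq_len(nf)
    cl <- cluster_once(x[fidx, idx, drop = FALSE])
    ind <- outer(cl, cl, "==")
    co_cluster[idx, idx] <- co_cluster[idx, idx] + ind
    co_sample[idx, idx] <- co_sample[idx, idx] + 1L
  }
  never <- co_sample == 0
  if (any(never[upper.tri(never)])) {
    warning(sum(never[upper.tri(never)]),
            " sample pair(s) never co-sampled; consensus set to 0 — ",
            "increase B or p_item")
  }
  M <- ifelse(co_sample > 0, co_cluster / co_sample, 0)
  diag(M) <- 1
  dimnames(M) <- list(samp_ids, samp_ids)

  labels <- stats::cutree(
    stats::hclust(stats::as.dist(1 - M), method = "average"), k = k)
  names(labels) <- samp_ids

  structure(list(k = k, B = B, p_item = p_item, p_feature = p_feature,
                 consensus_matrix = M,
                 labels = labels, cocluster_counts = co_cluster,
                 cosample_counts = co_sample, seed = seed, base = base),
            class = "consensus_run")
}

#' Proportion of ambiguous clustering (PAC)
#'
#' The empirical-CDF mass of the off-diagonal upper-triangle consensus
#' entries falling between `u1` and `u2`: `PAC = F(u2) - F(u1)`. Low PAC
#' indicates a stable clustering.
#'
#' @param M Consensus matrix (samples x samples).
#' @param u1,u2 Lower and upper ambiguity bounds.
#' @return PAC in [0, 1].
#' @export
compute_pac <- function(M, u1 = 0.1, u2 = 0.9) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  if (nrow(M) < 2L) stop("consensus matrix must cover at least 2 samples")
  x <- M[upper.tri(M)]
  mean(x <= u2) - mean(x <= u1)
}

# area under the consensus-CDF; basis of the delta-area audit statistic
consensus_cdf_area <- function(M) {
  x <- sort(M[upper.tri(M)])
  n <- length(x)
  grid <- c(0, x, 1)
  F_at <- c(0, seq_len(n) / n)      # CDF value on [grid[i], grid[i+1])
  sum(F_at * diff(grid))
}

#' Select the number of clusters from consensus runs
#'
#' Chooses `k = argmin PAC` (ties broken toward the smaller k). The
#' delta-area statistic (relative increase in consensus-CDF area, the
#' classic consensus-clustering audit plot) is reported alongside.
#'
#' @param runs List of [run_consensus()] results over distinct `k`.
#' @param u1,u2 PAC bounds.
#' @return List (class `k_selection`): `k` (candidates), `pac`, `cdf_area`,
#'   `delta_area`, `chosen_k`, `rule`.
#' @export
select_k <- function(runs, u1 = 0.1, u2 = 0.9) {
  if (length(runs) < 2L) stop("need at least 2 candidate values of k")
  ks <- vapply(runs, `[[`, 0L, "k")
  if (anyDuplicated(ks)) stop("duplicate candidate k")
  ord <- order(ks)
  runs <- runs[ord]; ks <- ks[ord]
  pac <- vapply(runs, function(r) compute_pac(r$consensus_matrix, u1, u2), 0)
  area <- vapply(runs, function(r) consensus_cdf_area(r$consensus_matrix), 0)
  delta <- c(NA_real_, diff(area) / utils::head(area, -1L))
  chosen <- ks[which.min(pac)]      # which.min takes the first (smaller k) tie
  structure(list(k = ks, pac = pac, cdf_area = area, delta_area = delta,
                 chosen_k = chosen, rule = "argmin PAC (tie -> smaller k)"),
            class = "k_selection")
}
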