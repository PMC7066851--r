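#' Single-sample gene-set enrichment scores (ssGSEA)
#'
#' Rank-based running-sum enrichment per sample and gene set, used here to
#' quantify the relative abundance of tumor-microenvironment cell types from
#' their marker sets. For each sample the N genes are ordered by expression
#' (descending; ties broken by gene id, lexicographic), the gene at position
#' i receives rank weight `z = N - i + 1`, and
#' \deqn{ES(S) = \sum_i \left[ P_{in}(i) - P_{out}(i) \right]}
#' where `P_in(i)` is the alpha-weighted cumulative fraction of set-gene
#' weight at positions <= i and `P_out(i)` the cumulative fraction of
#' non-set genes. Integer rank positions (not raw expression) are used as
#' weights, which makes the score invariant to monotone transforms of a
#' sample's expression.
#'
#' @param expr Genes x samples matrix.
#' @param sets Named list of gene-id vectors (see [read_gmt()]).
#' @param alpha Rank-weight exponent.
#' @param normalize Rescale the whole score matrix by its global
#'   `max - min` (the usual ssGSEA-norm convention); `"per_set"` rescales
#'   each set's row separately.
#' @param min_overlap Sets sharing fewer genes with `expr` are dropped with
#'   a warning.
#' @return List (class `enrichment_scores`): `scores` (sets x samples),
#'   `alpha`, `normalized`.
#' @export
ssgsea_scores <- function(expr, sets, alpha = 0.25, normalize = TRUE,
                          min_overlap = 2L) {
  stopifnot(is.matrix(expr), is.numeric(expr))
  if (ncol(expr) == 0L || nrow(expr) == 0L) stop("empty expression matrix")
  genes <- rownames(expr)
  N <- length(genes)
  sets_use <- lapply(sets, function(s) unique(s[s %in% genes]))
  keep <- lengths(sets_use) >= min_overlap
  if (!all(keep)) {
    warning("dropping ", sum(!keep), " set(s) with fewer than ",
            min_overlap, " genes in the expression matrix: ",
            paste(utils::head(names(sets)[!keep], 5L), collapse = ", "))
  }
  sets_use <- sets_use[keep]
  if (length(sets_use) == 0L) stop("no gene set overlaps the expression matrix")
  if (any(lengths(sets_use) == N)) {
    stop("gene set covering every gene: ",
         names(sets_use)[lengths(sets_use) == N][1L])
  }

  scores <- matrix(NA_real_, length(sets_use), ncol(expr),
                   dimnames = list(names(sets_use), colnames(expr)))
  w_all <- (N:1)^alpha
  in_set <- lapply(sets_use, function(s) genes %in% s)
  for (j in seq_len(ncol(expr))) {
    ord <- order(-expr[, j], genes)          # descending, ties by gene id
    for (si in seq_along(sets_use)) {
      ind <- in_set[[si]][ord]
      w <- w_all * ind
      p_in <- cumsum(w) / sum(w)
      p_out <- cumsum(!ind) / (N - sum(ind))
      scores[si, j] <- sum(p_in - p_out)
    }
  }
  normalized <- !identical(normalize, FALSE)
  if (identical(normalize, "per_set")) {
    rng <- apply(scores, 1L, function(r) diff(range(r)))
    scores <- scores / ifelse(rng == 0, 1, rng)
  } else if (normalized) {
    rng <- diff(range(scores))
    if (rng > 0) scores <- scores / rng
  }
  structure(list(scores = scores, alpha = alpha, normalized = normalized),
            class = "enrichment_scores")
}

#' Mean z-score signature
#'
#' Per-gene z-score across samples, then per-sample mean over the set genes.
#' Used for stromal/immune pathway panels (EMT, TGF-beta, angiogenesis and
#' the like).
#'
#' @param expr Genes x samples matrix.
#' @param set Character vector of gene ids (duplicates ignored).
#' @return Named numeric vector, one score per sample.
#' @export
zscore_signature <- function(expr, set) {
  set <- unique(set)
  present <- intersect(set, rownames(expr))
  if (length(present) < 1L) {
    stop("signature shares no genes with the expression matrix")
  }
  z <- zscore_rows(expr[present, , drop = FALSE], drop_constant = TRUE)
  if (nrow(z) == 0L) stop("all signature genes have zero variance")
  colMeans(z)
}
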