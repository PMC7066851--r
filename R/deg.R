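#' Empirical-Bayes moderated two-sample t-test
#'
#' Per gene: a pooled-variance two-sample comparison whose variance is shrunk
#' toward a common prior, `s2_tilde = (d0 * s0^2 + d_g * s2_g) / (d0 + d_g)`,
#' with the prior degrees of freedom `d0` and prior variance `s0^2` estimated
#' by method of moments on the log sample variances (the standard moderated-t
#' estimator: the log variances follow a scaled log-F under the hierarchical
#' model, so `d0` solves `trigamma(d0/2) = var(e) - mean(trigamma(d_g/2))`
#' for the centered log variances `e`). The moderated t has `d0 + d_g`
#' degrees of freedom; p-values are BH-adjusted over all genes.
#'
#' @param expr Genes x samples matrix (log2 scale).
#' @param samples_a,samples_b Sample ids of the two groups (>= 2 each).
#' @param prior_df Override the estimated `d0` (0 recovers the ordinary t;
#'   `Inf` gives full shrinkage to `s0^2`).
#' @param prior_var Override the estimated `s0^2` (required with
#'   `prior_df = Inf` unless estimable).
#' @return `data.frame` with one row per gene: group means, `log_fc`
#'   (mean_a - mean_b), ordinary `t_ord`, moderated `t_mod`, residual `df`,
#'   `s2` (sample variance), `s2_post`, `p`, `adj_p`; prior estimates in
#'   `attr(, "prior")` (`d0`, `s02`; `d0 = Inf` flags full shrinkage).
#' @export
moderated_ttest <- function(expr, samples_a, samples_b, prior_df = NULL,
                            prior_var = NULL) {
  stopifnot(is.matrix(expr))
  miss <- setdiff(c(samples_a, samples_b), colnames(expr))
  if (length(miss)) stop("sample(s) not in matrix: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  na <- length(samples_a); nb <- length(samples_b)
  if (na < 2L || nb < 2L) stop("each group needs at least 2 samples")
  xa <- expr[, samples_a, drop = FALSE]
  xb <- expr[, samples_b, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  d_g <- na + nb - 2L
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  s2 <- (ssa + ssb) / d_g
  scale_c <- sqrt(1 / na + 1 / nb)
  delta <- ma - mb
  t_ord <- ifelse(s2 > 0, delta / (sqrt(s2) * scale_c),
                  ifelse(delta == 0, 0, sign(delta) * Inf))

  if (is.null(prior_df) || is.null(prior_var)) {
    est <- fit_f_dist(s2, d_g)
    d0 <- prior_df %||% est$df_prior
    s02 <- prior_var %||% est$var_prior
  } else {
    d0 <- prior_df; s02 <- prior_var
  }

  if (d0 == 0) {
    s2_post <- s2
    df_total <- d_g
  } else if (is.infinite(d0)) {
    s2_post <- rep_len(s02, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (d0 * s02 + d_g * s2) / (d0 + d_g)
    df_total <- d0 + d_g
  }
  t_mod <- ifelse(s2_post > 0, delta / (sqrt(s2_post) * scale_c),
                  ifelse(delta == 0, 0, sign(delta) * Inf))
  p <- if (is.infinite(df_total)) 2 * stats::pnorm(-abs(t_mod)) else
    2 * stats::pt(-abs(t_mod), df = df_total)
  p[t_mod == 0] <- 1

  out <- data.frame(gene = rownames(expr), mean_a = ma, mean_b = mb,
                    log_fc = delta, t_ord = t_ord, t_mod = t_mod,
                    df = d_g, s2 = s2, s2_post = s2_post, p = p,
                    adj_p = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "prior") <- list(d0 = d0, s02 = s02)
  out
}

# Method-of-moments fit of the scaled-F prior for sample variances.
# E[log s2] = log(s02) + digamma(d/2) - log(d/2) + digamma(d0/2)... inverted
# per the standard moderated-t estimator; no positive solution => d0 = Inf
# (full shrinkage) with a message.
fit_f_dist <- function(s2, df1) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) stop("need at least 2 genes with positive variance")
  z <- log(s2[ok])
  e <- z - digamma(df1 / 2) + log(df1 / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df1 / 2)
  if (is.finite(evar) && evar > 0) {
    df2 <- 2 * trigamma_inverse(evar)
    s02 <- exp(emean + digamma(df2 / 2) - log(df2 / 2))
    list(df_prior = df2, var_prior = s02)
  } else {
    message("log-variance moments admit no finite prior df; ",
            "using full shrinkage (d0 = Inf)")
    list(df_prior = Inf, var_prior = exp(emean))
  }
}

# Newton inversion of the trigamma function (y > 0 -> x with trigamma(x)=y)
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2L)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j`, capped at 1, returned in the
#' original order.
#'
#' @param p Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values (FDR).
#' @export
bh_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Phenotype-related genes: overlap of pairwise DEG sets
#'
#' Each table's DEG set is `{gene : adj_p < alpha}`; the phenotype-related
#' genes are the intersection across all pairwise pattern comparisons
#' (A-vs-B, A-vs-C, B-vs-C), sorted lexicographically. `mode = "union"` is
#' offered as the permissive alternative reading.
#'
#' @param tables List of [moderated_ttest()] tables over one gene universe.
#' @param alpha Adjusted-p threshold (0.001 by default).
#' @param mode `"intersection"` (default) or `"union"`.
#' @return Character vector of gene ids.
#' @export
deg_overlap <- function(tables, alpha = 0.001,
                        mode = c("intersection", "union")) {
  mode <- match.arg(mode)
  if (length(tables) < 2L) stop("need at least 2 DEG tables")
  universes <- lapply(tables, function(t) sort(t$gene))
  if (!all(vapply(universes[-1L], identical, TRUE, universes[[1L]]))) {
    stop("DEG tables cover different gene universes")
  }
  sets <- lapply(tables, function(t) t$gene[t$adj_p < alpha])
  out <- Reduce(if (mode == "intersection") intersect else union, sets)
  sort(out)
}

#' Hypergeometric over-representation analysis
#'
#' For each set, `p = P(X >= k)` with
#' `X ~ Hypergeometric(N = |universe|, K = |set & universe|, n = |hits|)`;
#' BH adjustment across sets.
#'
#' @param hits Character vector of genes of interest (subset of `universe`).
#' @param universe Character vector, the background gene universe.
#' @param sets Named list of gene sets.
#' @return `data.frame`: `set`, `set_size` (in universe), `overlap`, `p`,
#'   `adj_p`, ordered by `p`.
#' @export
ora_hypergeometric <- function(hits, universe, sets) {
  hits <- unique(hits); universe <- unique(universe)
  if (!all(hits %in% universe)) {
    stop("hits outside the universe: ",
         paste(utils::head(setdiff(hits, universe), 5L), collapse = ", "))
  }
  N <- length(universe); n <- length(hits)
  K <- vapply(sets, function(s) length(intersect(s, universe)), 0L)
  k <- vapply(sets, function(s) length(intersect(s, hits)), 0L)
  p <- ifelse(K == 0, 1, stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE))
  out <- data.frame(set = names(sets), set_size = K, overlap = k, p = p,
                    adj_p = bh_adjust(p), row.names = NULL,
                    stringsAsFactors = FALSE)
  out[order(out$p, out$set), , drop = FALSE]
}
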