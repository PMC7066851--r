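#' Tumor mutation burden per sample
#'
#' Counts mutation records whose variant class is nonsilent, grouped by
#' sample; cohort samples without any record get a burden of 0. Counts (not
#' per-megabase rates) are used, since panel size is generally unavailable.
#'
#' @param mutations Mutation `data.frame` (see [read_maf_lite()]).
#' @param cohort_samples Character vector of all cohort sample ids.
#' @param nonsilent Variant classes counted (default [nonsilent_classes()]).
#' @return `data.frame`: `sample_id`, `tmb`; the class list in
#'   `attr(, "nonsilent")`.
#' @export
tmb_per_sample <- function(mutations, cohort_samples,
                           nonsilent = nonsilent_classes()) {
  bad <- setdiff(nonsilent, maf_variant_classes())
  if (length(bad)) stop("unknown variant class(es): ",
                        paste(bad, collapse = ", "))
  keep <- mutations$variant_class %in% nonsilent
  counts <- table(factor(mutations$sample_id[keep], levels = cohort_samples))
  out <- data.frame(sample_id = cohort_samples,
                    tmb = as.integer(counts),
                    stringsAsFactors = FALSE)
  attr(out, "nonsilent") <- nonsilent
  out
}

#' Per-gene mutation frequency
#'
#' Frequency = distinct mutated samples / cohort size, as a percentage
#' rounded to 2 decimals, sorted descending.
#'
#' @param mutations Mutation `data.frame`.
#' @param cohort_samples All cohort sample ids.
#' @param genes Optional gene subset to report (absent genes get 0%).
#' @return `data.frame`: `gene`, `n_mutated_samples`, `frequency_pct`.
#' @export
mutation_frequency <- function(mutations, cohort_samples, genes = NULL) {
  if (length(cohort_samples) == 0L) stop("empty cohort")
  mut <- mutations[mutations$sample_id %in% cohort_samples, , drop = FALSE]
  if (is.null(genes)) genes <- sort(unique(mut$gene))
  pairs <- unique(mut[, c("sample_id", "gene")])
  counts <- table(factor(pairs$gene, levels = genes))
  out <- data.frame(gene = genes,
                    n_mutated_samples = as.integer(counts),
                    stringsAsFactors = FALSE)
  out$frequency_pct <- round(100 * out$n_mutated_samples /
                               length(cohort_samples), 2L)
  out <- out[order(-out$n_mutated_samples, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Pairwise mutation co-occurrence / mutual-exclusivity tests
#'
#' For each unordered gene pair, a 2x2 table of sample-level mutated /
#' not-mutated status is tested by [fisher_exact_2x2()]; direction is
#' co-occurrence when the odds ratio exceeds 1, exclusivity otherwise; BH
#' adjustment over all pairs.
#'
#' @param mutations Mutation `data.frame`.
#' @param cohort_samples All cohort sample ids.
#' @param genes Genes to test pairwise (>= 2).
#' @return `data.frame`: `gene_a`, `gene_b`, `n_both`, `n_a_only`,
#'   `n_b_only`, `n_neither`, `odds_ratio`, `direction`, `p`, `adj_p`.
#' @export
cooccurrence_tests <- function(mutations, cohort_samples, genes) {
  genes <- unique(genes)
  if (length(genes) < 2L) stop("need at least 2 genes")
  mut <- mutations[mutations$sample_id %in% cohort_samples, , drop = FALSE]
  status <- vapply(genes, function(g) {
    cohort_samples %in% mut$sample_id[mut$gene == g]
  }, logical(length(cohort_samples)))
  pairs <- utils::combn(genes, 2L)
  rows <- apply(pairs, 2L, function(pr) {
    a <- status[, pr[1L]]; b <- status[, pr[2L]]
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                  2L, 2L, byrow = TRUE)
    ft <- fisher_exact_2x2(tab)
    data.frame(gene_a = pr[1L], gene_b = pr[2L],
               n_both = tab[1, 1], n_a_only = tab[1, 2],
               n_b_only = tab[2, 1], n_neither = tab[2, 2],
               odds_ratio = ft$odds_ratio,
               direction = if (!ft$or_defined) NA_character_ else
                 if (ft$odds_ratio > 1) "co-occurrence" else "exclusivity",
               p = ft$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  rownames(out) <- NULL
  out
}
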