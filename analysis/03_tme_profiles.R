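#!/usr/bin/env Rscript
# Quantify TME cell infiltration per sample by ssGSEA over the marker sets
# and summarize enrichment by m6A pattern; the expectation mirrored from the
# generating model is A = innate+stromal high (immune-excluded), B =
# adaptive high (inflamed), C = low.

suppressMessages(library(m6Apattern))

expr <- read_expression_tsv("results/cohort/expression.tsv")
markers <- read_gmt("results/cohort/markers.gmt")
labels <- read.delim("results/cluster_labels.tsv")

es <- ssgsea_scores(expr, markers)
write.table(data.frame(set = rownames(es$scores), es$scores,
                       check.names = FALSE),
            "results/tme_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

grp <- labels$cluster[match(colnames(es$scores), labels$sample_id)]
by_cluster <- t(apply(es$scores, 1, tapply, grp, mean))
cat("mean ssGSEA enrichment by consensus cluster:\n")
print(round(by_cluster, 3))
for (ct in rownames(es$scores)) {
  kw <- kruskal_wallis(es$scores[ct, ], grp)
  cat(sprintf("  %-18s Kruskal-Wallis H = %.1f, p = %.3g\n", ct, kw$H, kw$p))
}
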