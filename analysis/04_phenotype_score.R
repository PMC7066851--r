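#!/usr/bin/env Rscript
# Phenotype-related genes and the m6A score: pairwise moderated-t DEGs
# between the consensus clusters (BH-adjusted p < 0.001), intersection
# across comparisons, univariate Cox screen, PCA score (PC1 + PC2, oriented
# to a stromal marker set), and the maximally selected rank-statistic
# cutpoint.

suppressMessages(library(m6Apattern))

expr <- read_expression_tsv("results/cohort/expression.tsv")
clinical <- read_clinical_tsv("results/cohort/clinical.tsv")
markers <- read_gmt("results/cohort/markers.gmt")
labels <- read.delim("results/cluster_labels.tsv")

aligned <- align_cohort(expr, clinical)
expr <- aligned$expr; clinical <- aligned$clinical
grp <- labels$cluster[match(colnames(expr), labels$sample_id)]

cls <- sort(unique(grp))
tables <- list()
for (pr in utils::combn(cls, 2, simplify = FALSE)) {
  nm <- paste(pr, collapse = "_vs_")
  tables[[nm]] <- moderated_ttest(expr, colnames(expr)[grp == pr[1]],
                                  colnames(expr)[grp == pr[2]])
  write.table(tables[[nm]], sprintf("results/deg_%s.tsv", nm), sep = "\t",
              quote = FALSE, row.names = FALSE)
}
genes <- deg_overlap(tables, alpha = 0.001)
writeLines(genes, "results/phenotype_genes.txt")
cat("phenotype-related genes (intersection of pairwise DEG sets):",
    length(genes), "\n")

screen <- cox_screen(expr, clinical, genes, alpha = 0.05)
write.table(screen, "results/cox_screen.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
sig <- screen$gene[screen$keep]
cat("prognostic signature genes (Wald p < 0.05):", length(sig), "\n")

stromal <- zscore_signature(expr, markers$stromal_cell_04)
sr <- compute_m6ascore(expr, sig, orient_to = stromal)
cat(sprintf("variance explained: PC1 %.1f%%, PC2 %.1f%%\n",
            100 * sr$var_explained[1], 100 * sr$var_explained[2]))
write.table(data.frame(sample_id = names(sr$score), m6ascore = sr$score,
                       pc1 = sr$pc1, pc2 = sr$pc2),
            "results/m6ascore.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

cp <- max_stat_cutpoint(sr$score, clinical$os_time, clinical$os_event)
cat(sprintf("cutpoint %.4f (max |z| = %.2f), %d low / %d high\n",
            cp$cutpoint, cp$statistic, cp$n_low, cp$n_high))
jsonlite::write_json(list(cutpoint = cp$cutpoint,
                          statistic = cp$statistic,
                          n_low = cp$n_low, n_high = cp$n_high),
                     "results/cutpoint.json", auto_unbox = TRUE, digits = NA)
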