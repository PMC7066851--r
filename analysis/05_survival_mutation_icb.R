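#!/usr/bin/env Rscript
# Associations of the dichotomized m6A score: Kaplan-Meier / log-rank and
# Cox models for overall survival, tumor mutation burden, and checkpoint-
# blockade response.

suppressMessages(library(m6Apattern))

clinical <- read_clinical_tsv("results/cohort/clinical.tsv")
mutations <- read_maf_lite("results/cohort/mutations.maf.tsv")
sc <- read.delim("results/m6ascore.tsv")
cp <- jsonlite::read_json("results/cutpoint.json")

score <- setNames(sc$m6ascore, sc$sample_id)
clinical <- clinical[match(names(score), clinical$sample_id), ]
grp <- dichotomize_score(score, cp$cutpoint)

lr <- logrank_test(clinical$os_time, clinical$os_event, grp)
cat(sprintf("log-rank chi-square = %.2f (p = %.3g)\n", lr$chisq, lr$p))
for (g in c("low", "high")) {
  km <- km_estimate(clinical$os_time[grp == g], clinical$os_event[grp == g])
  cat(sprintf("  5-year survival, %s m6Ascore: %.1f%%\n", g,
              100 * survival_at(km, 60)))
}
uni <- cox_fit(clinical$os_time, clinical$os_event,
               data.frame(high_score = as.integer(grp == "high")))
cat(sprintf("HR high vs low: %.2f (95%% CI %.2f-%.2f)\n",
            uni$hr[1], uni$ci_lower[1], uni$ci_upper[1]))
multi <- cox_fit(clinical$os_time, clinical$os_event,
                 data.frame(high_score = as.integer(grp == "high"),
                            age = clinical$age, sex = clinical$sex))
cat("multivariable Cox (score group adjusted for age, sex):\n")
print(data.frame(term = names(multi$coef), hr = round(multi$hr, 3),
                 p = signif(multi$p, 3)), row.names = FALSE)

tmb <- tmb_per_sample(mutations, names(score))
rho <- spearman_corr(score[tmb$sample_id], tmb$tmb)
cat(sprintf("Spearman rho(m6Ascore, TMB) = %.3f (p = %.3g)\n",
            rho$rho, rho$p))
write.table(tmb, "results/tmb.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

responder <- ifelse(clinical$response == "R", 1L, 0L)
auc <- auc_rank(-score, responder)
cat(sprintf("AUC of low m6Ascore for ICB response: %.3f\n", auc))
tab <- table(grp, responder)
ft <- fisher_exact_2x2(matrix(as.integer(tab), 2, 2))
cat(sprintf("response rate low/high: %.0f%% / %.0f%% (Fisher p = %.3g)\n",
            100 * mean(responder[grp == "low"]),
            100 * mean(responder[grp == "high"]), ft$p))
jsonlite::write_json(list(logrank_chisq = lr$chisq, logrank_p = lr$p,
                          hr_high_vs_low = uni$hr[1],
                          tmb_spearman_rho = rho$rho, icb_auc = auc),
                     "results/associations.json", auto_unbox = TRUE,
                     digits = NA)
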