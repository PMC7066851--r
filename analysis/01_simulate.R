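#!/usr/bin/env Rscript
# Generate the default ACRG-like synthetic cohort (300 samples, 3 latent m6A
# modification patterns on 21 regulators, DEG block, TME marker structure,
# proportional-hazards survival, TMB, ICB response) and write it as plain
# text under results/cohort/.

suppressMessages(library(m6Apattern))

params <- sim_params(seed = 1)
cohort <- simulate_cohort(params)
write_cohort(cohort, "results/cohort")
writeLines(cohort$regulator_ids, "results/cohort/regulators.txt")

cat("cohort written to results/cohort/\n")
cat(sprintf("  genes x samples : %d x %d\n", nrow(cohort$expr),
            ncol(cohort$expr)))
cat(sprintf("  events          : %d/%d (%.0f%%)\n",
            sum(cohort$clinical$os_event), nrow(cohort$clinical),
            100 * mean(cohort$clinical$os_event)))
cat(sprintf("  mutation records: %d\n", nrow(cohort$mutations)))
print(table(latent_pattern = cohort$truth$latent_label))
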