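test_that("the PCA score matches the hand-worked SVD of two identical genes", {
  m <- rbind(G1 = c(1, 2, 3), G2 = c(1, 2, 3))
  colnames(m) <- paste0("S", 1:3)
  sr <- compute_m6ascore(m, c("G1", "G2"))
  expect_equal(unname(sr$pc1), c(-sqrt(2), 0, sqrt(2)))
  expect_equal(unname(sr$pc2), c(0, 0, 0))
  expect_equal(unname(sr$score), c(-sqrt(2), 0, sqrt(2)))
  expect_equal(unname(sr$loadings[, "PC1"]), c(1, 1) / sqrt(2))
  expect_equal(sr$var_explained[1], 1)
})

test_that("the score is consistent with its own loadings and input-order invariant", {
  co <- simulate_cohort(small_params(seed = 17))
  genes <- c(co$truth$deg_ids, co$regulator_ids)
  sr <- compute_m6ascore(co$expr, genes)
  # PC projections recomputed from returned loadings on the z-scored matrix
  z <- t(apply(co$expr[sr$genes, ], 1, function(v) (v - mean(v)) / sd(v)))
  expect_equal(unname(t(z) %*% sr$loadings[, "PC1"])[, 1],
               unname(sr$pc1), tolerance = 1e-10)
  expect_equal(sr$score, sr$pc1 + sr$pc2)

  # permuted gene list, duplicated ids, appended constant non-signature gene
  expr2 <- rbind(co$expr, CONST = rep(3, ncol(co$expr)))
  sr2 <- compute_m6ascore(expr2, c(rev(genes), genes[1]))
  expect_equal(sr2$score, sr$score, tolerance = 1e-8)

  flat <- matrix(5, 3, 4, dimnames = list(paste0("G", 1:3), paste0("S", 1:4)))
  expect_error(compute_m6ascore(flat, rownames(flat)), "nonzero variance")
  expect_error(compute_m6ascore(co$expr[, 1:2], genes), "3 samples")
})

test_that("the synthetic score tracks the latent score and orders patterns A > C > B", {
  co <- simulate_cohort(sim_params(seed = 2))
  lab <- co$truth$latent_label
  ids <- colnames(co$expr)
  tabs <- suppressMessages(lapply(list(c("A", "B"), c("A", "C"), c("B", "C")),
    function(pr) moderated_ttest(co$expr, ids[lab == pr[1]],
                                 ids[lab == pr[2]])))
  genes <- deg_overlap(tabs, alpha = 0.001)
  stromal <- zscore_signature(co$expr, co$cell_marker_sets$stromal_cell_04)
  sr <- compute_m6ascore(co$expr, genes, orient_to = stromal)
  r <- spearman_corr(sr$score, co$truth$latent_score)
  expect_gte(abs(r$rho), 0.8)
  m <- tapply(sr$score, lab, mean)
  expect_true(m[["A"]] > m[["C"]] && m[["C"]] > m[["B"]])
  expect_lt(kruskal_wallis(sr$score, lab)$p, 1e-6)
})

test_that("dichotomization respects the cutpoint and empty-group guard", {
  expect_equal(as.character(dichotomize_score(c(1, 2, 3), 2)),
               c("low", "low", "high"))
  expect_error(dichotomize_score(c(1, 2, 3), 3), "empty group")
  expect_error(dichotomize_score(c(1, 2, 3), 0.5), "empty group")

  set.seed(3)
  score <- rnorm(50); tt <- rexp(50, 0.1); ee <- rep(1, 50)
  cp <- max_stat_cutpoint(score, tt, ee)
  grp <- dichotomize_score(score, cp$cutpoint)
  expect_equal(unname(table(grp)["low"]), cp$n_low, ignore_attr = TRUE)
  expect_equal(unname(table(grp)["high"]), cp$n_high, ignore_attr = TRUE)
})

test_that("Spearman correlation matches rank-Pearson hand values", {
  expect_equal(spearman_corr(1:3, 3:1)$rho, -1)
  expect_equal(spearman_corr(1:3, 3:1)$p, 0)
  expect_equal(spearman_corr(1:4, c(2, 4, 6, 8))$rho, 1)
  expect_equal(spearman_corr(1:4, c(1, 3, 2, 4))$rho, 0.8)
  expect_error(spearman_corr(1:2, 2:1), "n >= 3")
  expect_error(spearman_corr(c(1, 2, 3), c(5, 5, 5)), "rank variance")
})

test_that("Kruskal-Wallis matches the rank-sum formula and null size", {
  kw <- kruskal_wallis(1:6, rep(c("A", "B", "C"), each = 2))
  expect_equal(kw$H, 32 / 7, tolerance = 1e-4)
  expect_equal(kw$H, 4.5714, tolerance = 1e-4)

  dup <- kruskal_wallis(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(dup$H, 0)
  expect_equal(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3))$p, 1)

  set.seed(21)
  reps <- 500L
  rej <- vapply(seq_len(reps), function(i) {
    kruskal_wallis(rnorm(60), rep(c("a", "b", "c"), each = 20))$p < 0.05
  }, NA)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 2 * se)
})

test_that("rank-sum U statistic and exact small-sample p behave as enumerated", {
  same <- wilcoxon_ranksum(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$U, 4.5)          # n1 n2 / 2 under identical multisets
  expect_gt(same$p, 0.9)

  expect_equal(wilcoxon_ranksum(c(9, 10), c(1, 2, 3))$U, 6)  # all greater
  lo <- wilcoxon_ranksum(c(1, 2), c(3, 4, 5))
  expect_equal(lo$U, 0)
  expect_equal(lo$p, 0.2)            # exact enumeration: 2/10
})

test_that("Fisher exact matches full table enumeration and margin conventions", {
  ft <- fisher_exact_2x2(matrix(c(3, 1, 1, 3), 2, byrow = TRUE))
  expect_equal(ft$p, 34 / 70)
  expect_equal(ft$odds_ratio, 9)

  anti <- fisher_exact_2x2(matrix(c(0, 5, 5, 0), 2, byrow = TRUE))
  expect_equal(anti$p, 2 / choose(10, 5))

  flat <- fisher_exact_2x2(matrix(c(2, 2, 2, 2), 2))
  expect_equal(flat$p, 1)
  expect_equal(flat$odds_ratio, 1)

  zero_margin <- fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2, byrow = TRUE))
  expect_equal(zero_margin$p, 1)
  expect_false(zero_margin$or_defined)
  expect_error(fisher_exact_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integers")
})

test_that("rank AUC handles separation, ties, and matches the ROC reference", {
  expect_equal(auc_rank(c(0.9, 0.8, 0.3, 0.2), c(1, 1, 0, 0)), 1.0)
  expect_equal(auc_rank(rep(0.5, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_error(auc_rank(1:4, c(1, 1, 1, 1)), "both classes")

  set.seed(6)
  s <- rnorm(100); lbl <- rbinom(100, 1, plogis(s))
  ref <- as.numeric(pROC::auc(pROC::roc(lbl, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_rank(s, lbl), ref, tolerance = 1e-10)
})

test_that("ICB response discrimination matches the generating-model AUC", {
  co <- simulate_cohort(sim_params(seed = 5))
  lab <- co$truth$latent_label
  ids <- colnames(co$expr)
  tabs <- suppressMessages(lapply(list(c("A", "B"), c("A", "C"), c("B", "C")),
    function(pr) moderated_ttest(co$expr, ids[lab == pr[1]],
                                 ids[lab == pr[2]])))
  genes <- deg_overlap(tabs, alpha = 0.001)
  stromal <- zscore_signature(co$expr, co$cell_marker_sets$stromal_cell_04)
  sr <- compute_m6ascore(co$expr, genes, orient_to = stromal)
  responder <- co$truth$responder[ids]
  auc_obs <- auc_rank(-sr$score, responder)

  # Monte-Carlo oracle: AUC of the generating latent score against responses
  # drawn from the true per-sample probabilities
  set.seed(123)
  auc_mc <- mean(vapply(1:200, function(i) {
    resp <- rbinom(length(ids), 1, co$truth$response_prob[ids])
    if (length(unique(resp)) < 2) return(NA_real_)
    auc_rank(-co$truth$latent_score[ids], resp)
  }, 0), na.rm = TRUE)
  expect_lt(abs(auc_obs - auc_mc), 0.05)
})
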