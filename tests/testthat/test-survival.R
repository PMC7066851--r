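test_that("Kaplan-Meier matches hand product-limit values and boundary cases", {
  km <- km_estimate(c(5, 10), c(1, 0))
  expect_equal(survival_at(km, 5), 0.5)
  expect_equal(survival_at(km, 10), 0.5)
  expect_equal(survival_at(km, 2), 1)

  km_c <- km_estimate(c(3, 6, 9), c(0, 0, 0))
  expect_true(all(km_c$surv == 1))

  expect_error(km_estimate(numeric(0), numeric(0)), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "> 0")

  # no censoring: step function equals the empirical survival
  set.seed(2)
  tt <- rexp(40)
  km_n <- km_estimate(tt, rep(1, 40))
  for (q in c(0.2, 0.8, 1.5)) {
    expect_equal(survival_at(km_n, q), mean(tt > q))
  }
  expect_true(all(diff(km_n$surv) <= 0))
})

test_that("Kaplan-Meier converges to the exponential survival function", {
  set.seed(31)
  lam <- 0.02
  tt <- rexp(2000, lam)
  km <- km_estimate(tt, rep(1, 2000))
  s60 <- survival_at(km, 60)
  truth <- exp(-lam * 60)
  expect_lt(abs(s60 - truth), 3 * sqrt(truth * (1 - truth) / 2000))
})

test_that("log-rank matches the hand-computed hypergeometric expectations", {
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c("g1", "g1", "g2", "g2"))
  expect_equal(lr$o_minus_e[1], 7 / 6, tolerance = 1e-4)
  expect_equal(lr$var[1, 1], 0.4722, tolerance = 1e-3)
  expect_equal(lr$chisq, (7 / 6)^2 / (0.25 + 2 / 9), tolerance = 1e-6)

  # duplicated data across groups: no signal
  tt <- c(2, 5, 7, 9); ee <- c(1, 0, 1, 1)
  lr0 <- logrank_test(c(tt, tt), c(ee, ee), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0)
  expect_equal(lr0$p, 1)

  # relabeling invariance
  set.seed(12)
  t2 <- rexp(30); e2 <- rbinom(30, 1, 0.7); g2 <- sample(c("x", "y"), 30, TRUE)
  expect_equal(logrank_test(t2, e2, g2)$chisq,
               logrank_test(t2, e2, ifelse(g2 == "x", "y", "x"))$chisq)
  expect_error(logrank_test(t2, e2, rep("x", 30)), "2 groups")
})

test_that("log-rank holds its nominal size under the null", {
  set.seed(77)
  reps <- 500L
  rej <- vapply(seq_len(reps), function(i) {
    tt <- rexp(200, 0.05)
    cc <- runif(200, 0, 40)
    grp <- rbinom(200, 1, 0.5)
    logrank_test(pmin(tt, cc), as.integer(tt <= cc), grp)$p < 0.05
  }, NA)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(rej) - 0.05), 2 * se)
})

test_that("Cox fit maximizes the Breslow partial likelihood on the 4-subject fixture", {
  tt <- c(1, 2, 3, 4); ee <- c(1, 1, 1, 1); x <- c(1, 0, 1, 0)
  fit <- cox_fit(tt, ee, x)
  beta_grid <- grid_search_cox(tt, ee, x)
  expect_equal(unname(fit$coef), beta_grid, tolerance = 2e-3)
  expect_equal(unname(fit$coef), 0.940, tolerance = 1e-2)
  expect_equal(unname(fit$hr), exp(fit$coef[[1]]))
  expect_true(fit$ci_lower <= fit$hr && fit$hr <= fit$ci_upper)
  # translation invariance of the partial likelihood
  fit_shift <- cox_fit(tt, ee, x + 5)
  expect_equal(fit_shift$coef, fit$coef, ignore_attr = TRUE, tolerance = 1e-8)
  # log-likelihood at the optimum is no worse than at zero
  expect_gte(fit$loglik[2], fit$loglik[1])
})

test_that("Cox fit guards degenerate inputs and flags separation", {
  tt <- c(1, 2, 3, 4); ee <- c(1, 1, 1, 1)
  expect_error(cox_fit(tt, ee, rep(2, 4)), "zero-variance")
  expect_error(cox_fit(tt, c(0, 0, 0, 0), c(1, 0, 1, 0)), "no events")
  # perfectly separating covariate: monotone likelihood
  sep <- suppressWarnings(cox_fit(c(1, 2, 3, 4, 5, 6),
                                  rep(1, 6), c(1, 1, 1, 0, 0, 0)))
  expect_false(sep$converged)
  expect_true(all(abs(sep$coef) <= 20))
})

test_that("Cox recovers a known log-hazard with near-nominal CI coverage", {
  set.seed(55)
  beta_true <- log(2)
  reps <- 200L
  est <- cover <- numeric(reps)
  for (i in seq_len(reps)) {
    x <- rnorm(500)
    tt <- rexp(500, 0.05 * exp(beta_true * x))
    cc <- runif(500, 0, 60)
    fit <- cox_fit(pmin(tt, cc), as.integer(tt <= cc), x)
    est[i] <- fit$coef[[1]]
    ci <- log(c(fit$ci_lower[[1]], fit$ci_upper[[1]]))
    cover[i] <- ci[1] <= beta_true && beta_true <= ci[2]
  }
  expect_lte(abs(mean(est) - beta_true), 0.05)
  expect_gte(mean(cover), 0.92)
  expect_lte(mean(cover), 0.98)
})

test_that("categorical covariates are one-hot encoded against the first level", {
  set.seed(9)
  tt <- rexp(60); ee <- rbinom(60, 1, 0.8)
  grp <- sample(c("b_mid", "a_ref", "c_top"), 60, TRUE)
  fit <- cox_fit(tt, ee, data.frame(arm = grp))
  expect_setequal(names(fit$coef), c("armb_mid", "armc_top"))
  ref <- survival::coxph(survival::Surv(tt, ee) ~ factor(grp),
                         ties = "breslow")
  expect_equal(unname(fit$coef), unname(coef(ref)), tolerance = 1e-6)
})

test_that("the univariate gene screen keeps prognostic genes and rejects noise", {
  co <- simulate_cohort(small_params(seed = 21, n_samples = 200L))
  expr <- co$expr
  # a gene tracking the latent hazard plus one pure-noise, one constant gene
  expr <- rbind(expr,
                TRACK = co$truth$latent_score + rnorm(200, 0, 0.2),
                NOISE = rnorm(200),
                FLAT = rep(1, 200))
  tab <- cox_screen(expr, co$clinical, c("TRACK", "NOISE", "FLAT"))
  expect_true(tab$keep[tab$gene == "TRACK"])
  expect_gt(tab$coef[tab$gene == "TRACK"], 0)
  expect_false(tab$keep[tab$gene == "FLAT"])
  expect_false(tab$converged[tab$gene == "FLAT"])
})

test_that("screening a pure-noise gene rejects at the nominal rate", {
  set.seed(14)
  reps <- 200L
  kept <- vapply(seq_len(reps), function(i) {
    n <- 100
    tt <- rexp(n, 0.04); cc <- runif(n, 0, 50)
    clin <- data.frame(sample_id = paste0("S", 1:n),
                       os_time = pmin(tt, cc),
                       os_event = as.integer(tt <= cc))
    expr <- matrix(rnorm(n), 1, n,
                   dimnames = list("G1", clin$sample_id))
    cox_screen(expr, clin, "G1")$keep
  }, NA)
  se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(mean(kept) - 0.05), 3 * se)
})

test_that("max-stat cutpoint matches exhaustive enumeration on the 4-subject fixture", {
  score <- c(1, 2, 3, 4); tt <- c(10, 9, 2, 1); ee <- rep(1, 4)
  cp <- max_stat_cutpoint(score, tt, ee, minprop = 0.25)
  expect_equal(cp$candidates, c(1, 2, 3))
  z_oracle <- vapply(c(1, 2, 3), function(c)
    m6Apattern:::logrank_z(tt, ee, score <= c)[["z"]], 0)
  expect_equal(cp$z, z_oracle)
  # hand enumeration: z(1) = -1.334, z(2) = -1.698, z(3) = -1.732
  expect_equal(cp$z[2], -1.698, tolerance = 1e-3)
  expect_equal(cp$cutpoint, 3)
  expect_equal(cp$statistic, 1.732, tolerance = 1e-3)
  expect_equal(cp$n_low, 3L)

  expect_error(max_stat_cutpoint(score, tt, ee, minprop = 0.6),
               "no admissible")
})

test_that("max-stat cutpoint is invariant under monotone score transforms", {
  set.seed(33)
  n <- 80
  score <- rnorm(n)
  tt <- rexp(n, 0.05 * exp(0.5 * score)); ee <- rep(1, n)
  cp <- max_stat_cutpoint(score, tt, ee)
  cp2 <- max_stat_cutpoint(exp(score), tt, ee)
  expect_equal(which(cp$candidates == cp$cutpoint),
               which(cp2$candidates == cp2$cutpoint))
  expect_equal(cp$statistic, cp2$statistic)
  expect_equal(exp(cp$cutpoint), cp2$cutpoint)
})

test_that("the maximal statistic is selection-biased under the null", {
  set.seed(66)
  reps <- 200L
  exceed <- vapply(seq_len(reps), function(i) {
    n <- 200
    score <- rnorm(n)
    tt <- rexp(n, 0.05); cc <- runif(n, 0, 40)
    cp <- max_stat_cutpoint(score, pmin(tt, cc), as.integer(tt <= cc))
    cp$statistic > 1.96
  }, NA)
  expect_gt(mean(exceed), 0.15)   # far above the naive 5%
})

test_that("a true hazard step at the 60th percentile is recovered", {
  hits <- vapply(1:10, function(s) {
    set.seed(400 + s)
    n <- 500
    score <- runif(n)
    step <- as.numeric(score > quantile(score, 0.6))
    tt <- rexp(n, 0.03 * exp(1.0 * step))
    cc <- runif(n, 0, 80)
    cp <- max_stat_cutpoint(score, pmin(tt, cc), as.integer(tt <= cc))
    q_rec <- mean(score <= cp$cutpoint)
    abs(q_rec - 0.6) <= 0.05
  }, NA)
  expect_gte(sum(hits), 8L)
})
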