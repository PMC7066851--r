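two_group_fixture <- function(n_genes = 50, na = 4, nb = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_genes * (na + nb)), n_genes,
              dimnames = list(paste0("G", seq_len(n_genes)),
                              paste0("S", seq_len(na + nb))))
  list(m = m, a = colnames(m)[1:na], b = colnames(m)[(na + 1):(na + nb)])
}

test_that("moderated t handles null genes and matches the shrinkage formula", {
  fx <- two_group_fixture()
  m <- fx$m
  m["G1", ] <- 7                      # identical means, zero variance
  tab <- suppressMessages(moderated_ttest(m, fx$a, fx$b))
  g1 <- tab[tab$gene == "G1", ]
  expect_equal(g1$t_mod, 0)
  expect_equal(g1$p, 1)

  # plug-in: s2 = 1, d_g = 4, d0 = 4, s0^2 = 2 -> posterior 1.5
  m2 <- matrix(0, 2, 6, dimnames = list(c("A", "B"), paste0("S", 1:6)))
  grp_a <- paste0("S", 1:3); grp_b <- paste0("S", 4:6)
  # gene A: residual SS = 4 over d_g = 4 -> s2 = 1
  m2["A", ] <- c(0, 1, 2, 5, 6, 7)    # within-group variance 1 each
  m2["B", ] <- c(0, 2, 4, 1, 3, 5)
  tab2 <- moderated_ttest(m2, grp_a, grp_b, prior_df = 4, prior_var = 2)
  expect_equal(tab2$s2[tab2$gene == "A"], 1)
  expect_equal(tab2$s2_post[tab2$gene == "A"], (4 * 2 + 4 * 1) / 8)
})

test_that("prior df limits recover the ordinary t and full shrinkage", {
  fx <- two_group_fixture(seed = 2)
  t0 <- moderated_ttest(fx$m, fx$a, fx$b, prior_df = 0, prior_var = 1)
  expect_equal(t0$t_mod, t0$t_ord)
  p_classic <- apply(fx$m, 1, function(v)
    stats::t.test(v[1:4], v[5:8], var.equal = TRUE)$p.value)
  expect_equal(t0$p, unname(p_classic), tolerance = 1e-12)

  tinf <- moderated_ttest(fx$m, fx$a, fx$b, prior_df = Inf, prior_var = 1.7)
  expect_true(all(tinf$s2_post == 1.7))
})

test_that("moderated t agrees with the established empirical-Bayes implementation", {
  fx <- two_group_fixture(n_genes = 300, na = 5, nb = 5, seed = 3)
  # heteroscedastic genes so the prior is informative
  fx$m <- fx$m * sqrt(rchisq(300, 5) / 5)
  tab <- moderated_ttest(fx$m, fx$a, fx$b)
  design <- cbind(1, rep(c(1, 0), each = 5))
  ebf <- limma::eBayes(limma::lmFit(fx$m, design))
  expect_equal(attr(tab, "prior")$d0, ebf$df.prior, tolerance = 1e-6)
  expect_equal(attr(tab, "prior")$s02, ebf$s2.prior, tolerance = 1e-6)
  expect_equal(tab$t_mod, unname(ebf$t[, 2]), tolerance = 1e-8)
  expect_equal(tab$p, unname(ebf$p.value[, 2]), tolerance = 1e-8)
})

test_that("moderated t rejects undersized groups", {
  fx <- two_group_fixture()
  expect_error(moderated_ttest(fx$m, fx$a[1], fx$b), "at least 2")
})

test_that("BH adjustment matches the step-up formula and is order-invariant", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(4)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bh_adjust(p), brute_bh(p))
    perm <- sample(seq_along(p))
    expect_equal(bh_adjust(p[perm]), bh_adjust(p)[perm])
  }
})

test_that("deg_overlap intersects pairwise DEG sets over one universe", {
  mk <- function(sig, universe = c("A", "B", "C", "D")) {
    data.frame(gene = universe, adj_p = ifelse(universe %in% sig, 1e-5, 0.5))
  }
  expect_equal(deg_overlap(list(mk(c("A", "B", "C")), mk(c("B", "C")),
                                mk(c("B", "C", "D")))), c("B", "C"))
  expect_equal(deg_overlap(list(mk(character(0)), mk(c("B", "C")))),
               character(0))
  expect_equal(deg_overlap(list(mk("A"), mk("B")), mode = "union"),
               c("A", "B"))
  expect_error(deg_overlap(list(mk("A"), mk("A", universe = c("A", "X")))),
               "universe")
})

test_that("phenotype-gene recovery on synthetic cohorts is sensitive and specific", {
  recalls <- fps <- numeric(0)
  for (s in 1:5) {
    co <- simulate_cohort(sim_params(seed = 60 + s))
    lab <- co$truth$latent_label
    ids <- colnames(co$expr)
    cls <- c("A", "B", "C")
    tabs <- suppressMessages(lapply(utils::combn(cls, 2, simplify = FALSE),
      function(pr) moderated_ttest(co$expr, ids[lab == pr[1]],
                                   ids[lab == pr[2]])))
    ov <- deg_overlap(tabs, alpha = 0.001)
    recalls <- c(recalls, mean(co$truth$deg_ids %in% ov))
    bg <- grep("^BG", rownames(co$expr), value = TRUE)
    fps <- c(fps, mean(bg %in% ov))
  }
  expect_true(all(recalls >= 0.8))
  expect_true(all(fps <= 0.01))
})

test_that("hypergeometric ORA matches exact tail enumeration", {
  sets <- list(hit4 = paste0("g", 1:5))
  universe <- paste0("g", 1:20)
  hits <- paste0("g", c(1:4, 10))
  out <- ora_hypergeometric(hits, universe, sets)
  expect_equal(out$p, 76 / 15504)
  expect_equal(out$p, brute_hyper_tail(4, 20, 5, 5))

  # k = 0 boundary equals its enumerated tail (p = 1 by convention of X >= 0)
  out0 <- ora_hypergeometric(paste0("g", 10:12), universe, sets)
  expect_equal(out0$p, brute_hyper_tail(0, 20, 5, 3))
  expect_equal(out0$p, 1)

  # disjoint set: K = 0 -> p = 1
  out_d <- ora_hypergeometric(hits, universe, list(far = c("x1", "x2")))
  expect_equal(out_d$p, 1)
  expect_error(ora_hypergeometric(c("g1", "zz"), universe, sets), "universe")
})
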