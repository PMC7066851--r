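#' Simulation parameters for a synthetic tumor cohort
#'
#' Defaults emulate an ACRG-like gastric-cancer cohort: ~300 samples carrying
#' three latent m6A modification patterns imprinted on 21 regulator genes, a
#' phenotype-related DEG block, immune/stromal cell-marker structure,
#' proportional-hazards survival tied to a latent score, mutation burden
#' anti-correlated with that score, and a Bernoulli checkpoint-blockade
#' response.
#'
#' @param n_samples Cohort size.
#' @param n_regulators Number of regulator genes carrying the pattern signal.
#' @param n_deg Size of the phenotype-related DEG block.
#' @param n_background Number of pure-noise background genes.
#' @param cluster_probs Mixing proportions of the three latent patterns
#'   (A, B, C); must sum to 1.
#' @param effect_size Mean shift delta between cluster templates, in units of
#'   the noise SD.
#' @param noise_sd Residual expression SD sigma (log2 scale).
#' @param n_cell_types Number of TME cell types with marker sets.
#' @param markers_per_cell_type Marker genes per cell type.
#' @param score_beta Log-hazard per unit latent score.
#' @param baseline_hazard Exponential baseline hazard (per month).
#' @param censor_horizon Upper bound of the uniform censoring time (months).
#' @param tmb_mu0,tmb_slope,tmb_dispersion Negative-binomial mutation burden:
#'   mean `exp(tmb_mu0 - tmb_slope * L)` with size `tmb_dispersion`.
#' @param response_gamma0,response_gamma1 Logistic response model:
#'   `P(responder) = plogis(response_gamma0 - response_gamma1 * L)`.
#' @param seed Master seed; one RNG stream per data layer is derived from it.
#' @return List of validated parameters (class `sim_params`).
#' @export
sim_params <- function(n_samples = 300L, n_regulators = 21L, n_deg = 200L,
                       n_background = 800L,
                       cluster_probs = c(A = 0.37, B = 0.33, C = 0.30),
                       effect_size = 1.5, noise_sd = 1.0,
                       n_cell_types = 8L, markers_per_cell_type = 15L,
                       score_beta = 0.7, baseline_hazard = 0.01,
                       censor_horizon = 120, tmb_mu0 = log(10),
                       tmb_slope = 0.8, tmb_dispersion = 2,
                       response_gamma0 = -0.4, response_gamma1 = 1.0,
                       seed = 1L) {
  p <- as.list(environment())
  stopifnot(length(p$cluster_probs) == 3L,
            abs(sum(p$cluster_probs)) - 1 < 1e-8,
            all(p$cluster_probs > 0),
            p$effect_size >= 0, p$noise_sd > 0, p$baseline_hazard > 0,
            p$censor_horizon > 0, p$tmb_dispersion > 0,
            p$n_samples >= 1, p$n_regulators >= 1, p$n_deg >= 1,
            p$n_background >= 1, p$n_cell_types >= 1,
            p$markers_per_cell_type >= 1)
  if (abs(sum(p$cluster_probs) - 1) > 1e-8) {
    stop("cluster_probs must sum to 1")
  }
  names(p$cluster_probs) <- c("A", "B", "C")
  structure(p, class = "sim_params")
}

# the 21 m6A regulators: 8 writers, 2 erasers, 11 readers
M6A_REGULATORS <- c(
  "METTL3", "METTL14", "RBM15", "RBM15B", "WTAP", "KIAA1429", "CBLL1",
  "ZC3H13", "ALKBH5", "FTO", "YTHDC1", "YTHDC2", "YTHDF1", "YTHDF2",
  "YTHDF3", "IGF2BP1", "HNRNPA2B1", "HNRNPC", "FMR1", "LRPPRC", "ELAVL1")

# per-label marker-set abundance shifts (log2 units); labels A/B/C.
# A: innate + stromal high (immune-excluded), B: adaptive high (inflamed),
# C: low overall. Values distinct within each row so marker-set enrichment
# is strictly ordered across labels.
cell_type_profiles <- function(n_cell_types) {
  base <- list(
    innate  = c(A = 1.5, B = 0.2, C = 0.6),
    stromal = c(A = 1.8, B = 0.1, C = 0.5),
    adaptive = c(A = 0.5, B = 1.6, C = 0.1))
  kind <- rep(c("innate", "innate", "innate", "stromal", "stromal",
                "adaptive", "adaptive", "adaptive"),
              length.out = n_cell_types)
  prof <- do.call(rbind, base[kind])
  rownames(prof) <- sprintf("%s_cell_%02d", kind, seq_len(n_cell_types))
  prof
}

#' Simulate a synthetic tumor cohort with recorded ground truth
#'
#' See [sim_params()] for the generating model. Expression layers:
#' regulator and DEG genes get cluster-dependent means
#' `delta * sigma * perm(1, 0, -1)` (a fresh permutation per gene, so every
#' pairwise cluster comparison is non-null); background genes are pure noise;
#' cell-type marker genes add a label-dependent abundance shift. The latent
#' score is `L = mu(label) + N(0, 0.25)` with `mu(A) = 1, mu(C) = 0,
#' mu(B) = -1`. Survival is exponential with hazard
#' `baseline_hazard * exp(score_beta * L)` under uniform censoring; mutation
#' burden is negative-binomial decreasing in `L`; response is Bernoulli with
#' a logistic link decreasing in `L`. Identical seeds give bit-identical
#' cohorts; each data layer has its own derived RNG stream.
#'
#' @param params A [sim_params()] object.
#' @return List (class `synthetic_cohort`) with `expr` (genes x samples,
#'   log2 scale), `clinical`, `mutations`, `cell_marker_sets`,
#'   `regulator_ids`, and `truth` (latent labels, latent score, true
#'   parameters, true DEG ids, marker abundances, response probabilities,
#'   negative-binomial TMB draws).
#' @export
simulate_cohort <- function(params = sim_params()) {
  if (!inherits(params, "sim_params")) params <- do.call(sim_params, params)
  p <- params
  seeds <- derive_seeds(p$seed, 5L)
  n <- p$n_samples
  sample_ids <- sprintf("S%04d", seq_len(n))
  labels_lv <- c("A", "B", "C")

  # --- layer 1: latent labels and latent score ---------------------------
  set.seed(seeds[1L])
  label <- sample(labels_lv, n, replace = TRUE, prob = p$cluster_probs)
  mu_score <- c(A = 1, B = -1, C = 0)
  score_noise <- stats::rnorm(n, 0, sqrt(0.25))
  latent <- mu_score[label] + score_noise

  # --- layer 2: expression ----------------------------------------------
  set.seed(seeds[2L])
  reg_ids <- if (p$n_regulators == 21L) M6A_REGULATORS else
    sprintf("REG%03d", seq_len(p$n_regulators))
  deg_ids <- sprintf("DEG%04d", seq_len(p$n_deg))
  bg_ids <- sprintf("BG%04d", seq_len(p$n_background))
  prof <- cell_type_profiles(p$n_cell_types)
  marker_ids <- as.vector(vapply(seq_len(p$n_cell_types), function(ct) {
    sprintf("%s_MK%02d", rownames(prof)[ct], seq_len(p$markers_per_cell_type))
  }, character(p$markers_per_cell_type)))
  gene_ids <- c(reg_ids, deg_ids, bg_ids, marker_ids)
  n_genes <- length(gene_ids)

  baseline <- stats::rnorm(n_genes, mean = 6, sd = 0.5)
  names(baseline) <- gene_ids
  expr <- matrix(stats::rnorm(n_genes * n, 0, p$noise_sd),
                 nrow = n_genes, dimnames = list(gene_ids, sample_ids))
  expr <- expr + baseline

  # regulator templates: permutations of (1, 0, -1) scaled by delta * sigma,
  # assigned in balanced proportions across the six permutations so the
  # three patterns are exchangeable (no two a priori more similar; with 21
  # regulators the inter-centroid distances are exactly equal). Every
  # pairwise cluster contrast is non-null.
  shift <- p$effect_size * p$noise_sd
  perms <- list(c(1, 0, -1), c(1, -1, 0), c(0, 1, -1),
                c(0, -1, 1), c(-1, 1, 0), c(-1, 0, 1))
  templates <- do.call(rbind,
    perms[sample(rep_len(1:6, p$n_regulators))])
  dimnames(templates) <- list(reg_ids, labels_lv)
  expr[reg_ids, ] <- expr[reg_ids, ] + shift * templates[, label, drop = FALSE]

  # DEG block: phenotype-related genes follow the latent-score cluster
  # means mu(A)=1, mu(B)=-1, mu(C)=0, each gene up- or down-regulated
  # (random direction) -- all pairwise contrasts non-null, and the leading
  # principal component of the block recovers the latent score.
  deg_dir <- sample(c(1, -1), p$n_deg, replace = TRUE)
  deg_templates <- outer(deg_dir, mu_score[labels_lv])
  dimnames(deg_templates) <- list(deg_ids, labels_lv)
  expr[deg_ids, ] <- expr[deg_ids, ] +
    shift * deg_templates[, label, drop = FALSE]

  # cell-type marker shifts follow label-specific abundances
  abund <- prof[, label, drop = FALSE]   # cell types x samples
  colnames(abund) <- sample_ids
  for (ct in seq_len(p$n_cell_types)) {
    ids <- marker_ids[((ct - 1L) * p$markers_per_cell_type + 1L):
                        (ct * p$markers_per_cell_type)]
    expr[ids, ] <- expr[ids, ] + rep(abund[ct, ], each = length(ids))
  }

  marker_sets <- lapply(seq_len(p$n_cell_types), function(ct) {
    marker_ids[((ct - 1L) * p$markers_per_cell_type + 1L):
                 (ct * p$markers_per_cell_type)]
  })
  names(marker_sets) <- rownames(prof)

  # --- layer 3: survival -------------------------------------------------
  set.seed(seeds[3L])
  hazard <- p$baseline_hazard * exp(p$score_beta * latent)
  t_event <- stats::rexp(n, rate = hazard)
  t_cens <- stats::runif(n, 0, p$censor_horizon)
  os_time <- pmin(t_event, t_cens)
  os_event <- as.integer(t_event <= t_cens)
  age <- round(stats::rnorm(n, 62, 10))
  sex <- sample(c("F", "M"), n, replace = TRUE)

  # --- layer 4: mutations ------------------------------------------------
  set.seed(seeds[4L])
  tmb_mean <- exp(p$tmb_mu0 - p$tmb_slope * latent)
  tmb <- stats::rnbinom(n, size = p$tmb_dispersion, mu = tmb_mean)
  nonsil <- nonsilent_classes()
  n_silent <- stats::rpois(n, 2)
  rec_sample <- rep(sample_ids, tmb + n_silent)
  rec_class <- unlist(lapply(seq_len(n), function(i) {
    c(sample(nonsil, tmb[i], replace = TRUE),
      rep("Silent", n_silent[i]))
  }), use.names = FALSE)
  rec_gene <- sample(gene_ids, length(rec_sample), replace = TRUE)
  mutations <- data.frame(sample_id = rec_sample, gene = rec_gene,
                          variant_class = rec_class,
                          stringsAsFactors = FALSE)

  # --- layer 5: immunotherapy response ----------------------------------
  set.seed(seeds[5L])
  p_resp <- stats::plogis(p$response_gamma0 - p$response_gamma1 * latent)
  responder <- stats::rbinom(n, 1L, p_resp)

  clinical <- data.frame(sample_id = sample_ids, os_time = os_time,
                         os_event = os_event, age = age, sex = sex,
                         response = ifelse(responder == 1L, "R", "NR"),
                         stringsAsFactors = FALSE)

  truth <- list(latent_label = stats::setNames(label, sample_ids),
                latent_score = stats::setNames(latent, sample_ids),
                score_beta = p$score_beta,
                deg_ids = deg_ids,
                deg_direction = stats::setNames(deg_dir, deg_ids),
                regulator_templates = templates,
                cell_abundance = abund,
                cell_profiles = prof,
                tmb_draw = stats::setNames(tmb, sample_ids),
                response_prob = stats::setNames(p_resp, sample_ids),
                responder = stats::setNames(responder, sample_ids))

  structure(list(expr = expr, clinical = clinical, mutations = mutations,
                 cell_marker_sets = marker_sets, regulator_ids = reg_ids,
                 truth = truth, params = p),
            class = "synthetic_cohort")
}

#' Write a synthetic cohort to a directory of plain-text files
#'
#' Writes `expression.tsv`, `clinical.tsv`, `mutations.maf.tsv`,
#' `markers.gmt` and `truth.json`.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_tsv(cohort$expr, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$clinical, file.path(dir, "clinical.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_maf_lite(cohort$mutations, file.path(dir, "mutations.maf.tsv"))
  write_gmt(cohort$cell_marker_sets, file.path(dir, "markers.gmt"))
  truth <- cohort$truth
  truth$regulator_templates <- as.data.frame(truth$regulator_templates)
  named <- vapply(truth, function(v)
    is.atomic(v) && is.null(dim(v)) && !is.null(names(v)), NA)
  truth[named] <- lapply(truth[named], as.list)
  truth$cell_abundance <- NULL  # large, reconstructable from profiles+labels
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
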