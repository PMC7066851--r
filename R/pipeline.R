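#' Build a pipeline configuration
#'
#' Inputs may be file paths (TSV / GMT / MAF-lite) or in-memory objects of
#' the same shapes. Only expression, clinical and the regulator list are
#' required; stages whose inputs are absent (no markers, no mutations, no
#' response column) are skipped and recorded as skipped.
#'
#' @param expression Genes x samples matrix or TSV path (log2 scale).
#' @param clinical Clinical `data.frame` or TSV path.
#' @param regulators Character vector of regulator gene ids, or a file of
#'   one id per line.
#' @param markers_gmt Optional gene-set list or GMT path (TME cell markers).
#' @param mutations Optional mutation `data.frame` or MAF-lite path.
#' @param response_column Clinical column holding the binary therapy
#'   response (values `R`/`NR`, or CR/PR vs SD/PD, or 1/0).
#' @param k_min,k_max Candidate cluster numbers for consensus clustering.
#' @param consensus_B Resampling repetitions (1000 for production runs).
#' @param p_item Sample-inclusion fraction per resample.
#' @param p_feature Feature-inclusion fraction per resample; the default
#'   0.8 resamples the regulator panel as well, so that a forced merge of
#'   two genuine patterns at too-small k shows up as consensus ambiguity.
#' @param deg_alpha Adjusted-p threshold for phenotype-related genes.
#' @param screen_alpha Wald threshold for the univariate Cox gene screen.
#' @param minprop Minimum group fraction for the score cutpoint.
#' @param orient_to_set Optional name of a marker set (in `markers_gmt`)
#'   whose [zscore_signature()] orients the m6A score: the score is flipped,
#'   if needed, to correlate positively with it (e.g. a stromal panel, so
#'   that high score means stromal/immune-excluded).
#' @param seed Master seed; all pipeline randomness derives from it.
#' @param out_dir Optional output directory for `report.json` and per-stage
#'   TSVs; `NULL` keeps everything in memory.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(expression, clinical, regulators,
                            markers_gmt = NULL, mutations = NULL,
                            response_column = "response",
                            k_min = 2L, k_max = 5L, consensus_B = 1000L,
                            p_item = 0.8, p_feature = 0.8, deg_alpha = 0.001,
                            screen_alpha = 0.05, minprop = 0.1,
                            orient_to_set = NULL, seed = 1L,
                            out_dir = NULL) {
  cfg <- as.list(environment())
  stopifnot(cfg$k_min >= 2L, cfg$k_max >= cfg$k_min,
            cfg$consensus_B >= 1L, cfg$p_item > 0, cfg$p_item <= 1,
            cfg$p_feature > 0, cfg$p_feature <= 1,
            cfg$deg_alpha > 0, cfg$screen_alpha > 0,
            cfg$minprop > 0, cfg$minprop < 0.5)
  for (f in c("expression", "clinical", "regulators", "markers_gmt",
              "mutations")) {
    v <- cfg[[f]]
    if (is.character(v) && length(v) == 1L && !file.exists(v)) {
      stop("config path for '", f, "' does not exist: ", v)
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipeline_config()]; `overrides` (e.g. from
#' the command line) take precedence over file keys.
#'
#' @param path YAML file.
#' @param overrides Named list of overriding values.
#' @return `pipeline_config`.
#' @export
read_pipeline_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  do.call(pipeline_config, cfg)
}

load_input <- function(x, loader) if (is.character(x) && length(x) == 1L)
  loader(x) else x

#' Run the full m6A-pattern analysis
#'
#' Stages, in order: cohort alignment; consensus clustering of the regulator
#' genes over `k_min..k_max` with PAC-based selection of k; ssGSEA TME
#' scores (if marker sets given); pairwise moderated-t DEGs between the
#' chosen clusters and their intersection (phenotype-related genes);
#' univariate Cox screening of those genes; the PCA m6A score; maximally
#' selected rank-statistic cutpoint and dichotomization; Kaplan-Meier /
#' log-rank / Cox summaries of the score groups (including 60-month
#' survival); mutation-burden associations (if mutations given); and
#' immune-checkpoint-blockade response associations (if a response column is
#' present). Stage failures abort with the stage name; outputs already
#' written are kept.
#'
#' @param config A [pipeline_config()] (or YAML path).
#' @return List of class `report_bundle` with one entry per stage plus
#'   `stages` (status per stage) and `config_echo`; written to
#'   `report.json` when `out_dir` is set.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  report <- list(stages = list(),
                 config_echo = config_echo(config))
  seeds <- derive_seeds(config$seed, 2L)
  write_tsv <- function(df, name) {
    if (!is.null(out_dir)) {
      utils::write.table(df, file.path(out_dir, name), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
  }
  run_stage <- function(name, fun) {
    res <- tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    report$stages[[name]] <<- "completed"
    res
  }
  skip_stage <- function(name) report$stages[[name]] <<- "skipped"

  # --- inputs & alignment -----------------------------------------------
  expr <- load_input(config$expression, read_expression_tsv)
  clinical <- load_input(config$clinical, read_clinical_tsv)
  clinical <- validate_clinical(clinical)
  regulators <- load_input(config$regulators, function(p)
    readLines(p, warn = FALSE))
  mutations <- load_input(config$mutations, read_maf_lite)
  markers <- load_input(config$markers_gmt, read_gmt)
  aligned <- run_stage("align", function()
    align_cohort(expr, clinical, mutations))
  expr <- aligned$expr; clinical <- aligned$clinical
  mutations <- aligned$mutations
  samples <- colnames(expr)

  # --- consensus clustering ---------------------------------------------
  cluster <- run_stage("consensus_clustering", function() {
    ks <- config$k_min:config$k_max
    runs <- lapply(seq_along(ks), function(i)
      run_consensus(expr, regulators, k = ks[i], B = config$consensus_B,
                    p_item = config$p_item, p_feature = config$p_feature,
                    seed = seeds[1L] + i))
    sel <- select_k(runs)
    labels <- runs[[match(sel$chosen_k, ks)]]$labels
    list(selection = sel, labels = labels)
  })
  labels <- cluster$labels
  report$k_selection <- list(k = cluster$selection$k,
                             pac = cluster$selection$pac,
                             delta_area = cluster$selection$delta_area,
                             chosen_k = cluster$selection$chosen_k)
  report$cluster_sizes <- as.list(table(labels))
  write_tsv(data.frame(sample_id = samples, cluster = unname(labels)),
            "cluster_labels.tsv")

  # --- TME enrichment ----------------------------------------------------
  if (is.null(markers)) {
    skip_stage("tme_scores")
  } else {
    tme <- run_stage("tme_scores", function()
      ssgsea_scores(expr, markers))
    report$tme_score_summary <- lapply(
      split(seq_len(ncol(tme$scores)), labels[colnames(tme$scores)]),
      function(idx) round(rowMeans(tme$scores[, idx, drop = FALSE]), 6))
    write_tsv(data.frame(set = rownames(tme$scores), tme$scores,
                         check.names = FALSE), "tme_scores.tsv")
  }

  # --- phenotype-related genes ------------------------------------------
  pheno <- run_stage("phenotype_genes", function() {
    cls <- sort(unique(labels))
    pairs <- utils::combn(cls, 2L, simplify = FALSE)
    tables <- lapply(pairs, function(pr)
      moderated_ttest(expr, samples[labels == pr[1L]],
                      samples[labels == pr[2L]]))
    names(tables) <- vapply(pairs, paste, "", collapse = "_vs_")
    genes <- if (length(tables) == 1L) {
      sort(tables[[1L]]$gene[tables[[1L]]$adj_p < config$deg_alpha])
    } else {
      deg_overlap(tables, alpha = config$deg_alpha)
    }
    list(tables = tables, genes = genes)
  })
  report$n_phenotype_genes <- length(pheno$genes)
  if (!is.null(out_dir)) {
    for (nm in names(pheno$tables)) {
      write_tsv(pheno$tables[[nm]], paste0("deg_", nm, ".tsv"))
    }
    writeLines(pheno$genes, file.path(out_dir, "phenotype_genes.txt"))
  }
  if (length(pheno$genes) < 2L) {
    stop("pipeline stage 'phenotype_genes' failed: fewer than 2 ",
         "phenotype-related genes at alpha = ", config$deg_alpha,
         call. = FALSE)
  }

  # --- Cox screen --------------------------------------------------------
  screen <- run_stage("cox_screen", function()
    cox_screen(expr, clinical, pheno$genes, alpha = config$screen_alpha))
  sig_genes <- screen$gene[screen$keep]
  report$n_signature_genes <- length(sig_genes)
  write_tsv(screen, "cox_screen.tsv")
  if (length(sig_genes) < 2L) {
    sig_genes <- pheno$genes
    report$stages[["cox_screen"]] <- "completed (screen kept < 2 genes; full phenotype set used)"
  }

  # --- m6A score ---------------------------------------------------------
  sr <- run_stage("m6ascore", function() {
    orient <- NULL
    if (!is.null(config$orient_to_set)) {
      if (is.null(markers) || !config$orient_to_set %in% names(markers)) {
        stop("orient_to_set '", config$orient_to_set,
             "' not found in marker sets")
      }
      orient <- zscore_signature(expr, markers[[config$orient_to_set]])
    }
    compute_m6ascore(expr, sig_genes, orient_to = orient)
  })
  report$score_summary <- list(
    n_genes = length(sr$genes),
    var_explained = round(sr$var_explained, 6),
    orientation = sr$orientation)
  write_tsv(data.frame(sample_id = names(sr$score), m6ascore = sr$score,
                       pc1 = sr$pc1, pc2 = sr$pc2), "m6ascore.tsv")
  write_tsv(data.frame(gene = rownames(sr$loadings), sr$loadings),
            "pca_loadings.tsv")

  # --- cutpoint & survival ----------------------------------------------
  cut <- run_stage("cutpoint", function()
    max_stat_cutpoint(sr$score, clinical$os_time, clinical$os_event,
                      minprop = config$minprop))
  group <- dichotomize_score(sr$score, cut$cutpoint)
  report$cutpoint <- list(value = cut$cutpoint, statistic = cut$statistic,
                          n_low = cut$n_low, n_high = cut$n_high)

  surv <- run_stage("survival", function() {
    lr <- logrank_test(clinical$os_time, clinical$os_event, group)
    km <- lapply(split(seq_along(group), group), function(idx)
      km_estimate(clinical$os_time[idx], clinical$os_event[idx]))
    s60 <- vapply(km, survival_at, 0, t = 60)
    uni <- cox_fit(clinical$os_time, clinical$os_event,
                   data.frame(high_score = as.integer(group == "high")))
    covs <- intersect(c("age", "sex"), colnames(clinical))
    multi <- if (length(covs)) {
      cox_fit(clinical$os_time, clinical$os_event,
              cbind(data.frame(high_score = as.integer(group == "high")),
                    clinical[, covs, drop = FALSE]))
    } else NULL
    list(logrank = lr, km = km, s60 = s60, uni = uni, multi = multi)
  })
  report$survival <- list(
    logrank_chisq = surv$logrank$chisq, logrank_p = surv$logrank$p,
    surv_60mo = as.list(round(surv$s60, 6)),
    hr_high_vs_low = surv$uni$hr[[1L]],
    hr_ci = c(surv$uni$ci_lower[[1L]], surv$uni$ci_upper[[1L]]),
    multivariable = if (!is.null(surv$multi)) list(
      coef = as.list(round(surv$multi$coef, 6)),
      hr = as.list(round(surv$multi$hr, 6)),
      p = as.list(signif(surv$multi$p, 6))) else NULL)

  # --- mutation burden ---------------------------------------------------
  if (is.null(mutations) || nrow(mutations) == 0L) {
    skip_stage("mutation_tmb")
  } else {
    mut <- run_stage("mutation_tmb", function() {
      tmb <- tmb_per_sample(mutations, samples)
      rho <- spearman_corr(sr$score[tmb$sample_id], tmb$tmb)
      freq <- mutation_frequency(mutations, samples)
      kw <- kruskal_wallis(tmb$tmb, labels[tmb$sample_id])
      list(tmb = tmb, rho = rho, freq = freq, kw = kw)
    })
    report$tmb <- list(score_tmb_spearman_rho = mut$rho$rho,
                       score_tmb_spearman_p = mut$rho$p,
                       tmb_by_cluster_kw_p = mut$kw$p)
    write_tsv(mut$tmb, "tmb.tsv")
    write_tsv(mut$freq, "gene_mutation_frequency.tsv")
  }

  # --- immunotherapy response -------------------------------------------
  resp_col <- config$response_column
  if (is.null(resp_col) || !resp_col %in% colnames(clinical)) {
    skip_stage("icb_response")
  } else {
    icb <- run_stage("icb_response", function() {
      responder <- parse_response(clinical[[resp_col]])
      if (length(unique(stats::na.omit(responder))) < 2L) {
        stop("response column has a single class")
      }
      ok <- !is.na(responder)
      auc <- auc_rank(-sr$score[ok], responder[ok])
      wt <- wilcoxon_ranksum(sr$score[ok][responder[ok] == 1L],
                             sr$score[ok][responder[ok] == 0L])
      tab <- table(group = group[ok], responder = responder[ok])
      ft <- fisher_exact_2x2(matrix(as.integer(tab), 2L, 2L))
      rates <- tapply(responder[ok], group[ok], mean)
      list(auc = auc, wt = wt, fisher = ft, rates = rates)
    })
    report$icb <- list(
      auc_low_score_predicts_response = icb$auc,
      score_by_response_wilcoxon_p = icb$wt$p,
      response_rate = as.list(round(icb$rates, 6)),
      response_by_group_fisher_p = icb$fisher$p,
      response_by_group_or = icb$fisher$odds_ratio)
  }

  report$versions <- list(m6Apattern = as.character(
    utils::packageVersion("m6Apattern")))
  class(report) <- "report_bundle"
  if (!is.null(out_dir)) {
    jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
  }
  invisible(report)
}

# normalize a response column to 1 (responder) / 0 / NA
parse_response <- function(x) {
  if (is.numeric(x)) return(ifelse(x %in% c(0, 1), as.integer(x), NA_integer_))
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA_integer_, length(up))
  out[up %in% c("R", "RESPONDER", "CR", "PR", "CR/PR", "1", "TRUE", "YES")] <- 1L
  out[up %in% c("NR", "NON-RESPONDER", "NONRESPONDER", "SD", "PD", "SD/PD",
                "0", "FALSE", "NO")] <- 0L
  out
}

# config echo with paths kept and in-memory objects summarized; the output
# directory is omitted so reports are byte-identical across locations
config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$out_dir <- NULL
  lapply(cfg, function(v) {
    if (is.character(v) || is.numeric(v) || is.logical(v) || is.null(v)) {
      v
    } else {
      paste0("<in-memory ", class(v)[1L], ">")
    }
  })
}
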