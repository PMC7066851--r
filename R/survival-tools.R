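#' Kaplan-Meier product-limit estimate
#'
#' Thin wrapper over [survival::survfit()] exposing the event-time grid,
#' at-risk and event counts, the right-continuous survival step function and
#' its Greenwood variance.
#'
#' @param times Strictly positive follow-up times (months).
#' @param events 0/1 event indicators.
#' @return List (class `km_curve`): `time`, `n_risk`, `n_event`, `surv`,
#'   `greenwood_var`.
#' @export
km_estimate <- function(times, events) {
  check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "none")
  structure(list(time = fit$time, n_risk = fit$n.risk, n_event = fit$n.event,
                 surv = fit$surv,
                 greenwood_var = (fit$surv * fit$std.err)^2),
            class = "km_curve")
}

check_surv <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  stopifnot(length(times) == length(events))
  if (any(!is.finite(times) | times <= 0)) stop("times must be > 0")
  if (!all(events %in% c(0, 1))) stop("events must be 0 or 1")
  invisible(TRUE)
}

#' Survival probability at a time point
#'
#' Right-continuous step value of a [km_estimate()] curve: `S(t) = 1` before
#' the first event time.
#'
#' @param curve A `km_curve`.
#' @param t Time point (same units as the curve).
#' @return `S(t)`.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  vapply(t, function(tt) {
    i <- findInterval(tt, curve$time)
    if (i == 0L) 1 else curve$surv[i]
  }, 0)
}

#' Log-rank test of survival differences between groups
#'
#' Hypergeometric expected events at each distinct event time via
#' [survival::survdiff()]; chi-square with k - 1 degrees of freedom.
#'
#' @param times,events Survival input.
#' @param groups Group labels (>= 2 non-empty groups).
#' @return List (class `logrank_test`): `observed`, `expected`, `o_minus_e`,
#'   `var` (full variance matrix), `chisq`, `df`, `p`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv(times, events)
  groups <- as.factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) == 0L)) stop("empty group")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- nlevels(groups) - 1L
  structure(list(observed = as.vector(sd$obs), expected = as.vector(sd$exp),
                 o_minus_e = as.vector(sd$obs - sd$exp),
                 var = sd$var, chisq = sd$chisq, df = df,
                 p = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
                 groups = levels(groups)),
            class = "logrank_test")
}

#' Cox proportional-hazards fit
#'
#' Breslow partial likelihood maximized by [survival::coxph()] (Newton
#' iteration); categorical covariates are one-hot encoded against the
#' lexicographically first level. Monotone-likelihood separation is flagged:
#' coefficients are capped at +/- 20 and `converged` is set `FALSE`.
#'
#' @param times,events Survival input (>= 1 event).
#' @param covariates Numeric vector/matrix or `data.frame` (factors and
#'   characters are one-hot encoded).
#' @return List (class `cox_fit`): `coef`, `se`, `hr`, `ci_lower`,
#'   `ci_upper` (95% Wald), `z`, `p`, `loglik` (at 0 and at the optimum),
#'   `converged`, `iterations`, `n`, `n_event`.
#' @export
cox_fit <- function(times, events, covariates) {
  check_surv(times, events)
  if (sum(events) < 1) stop("no events")
  X <- encode_covariates(covariates, n = length(times))
  const <- apply(X, 2L, function(v) stats::sd(v) == 0)
  if (any(const)) {
    stop("zero-variance covariate(s): ",
         paste(colnames(X)[const], collapse = ", "))
  }
  fit <- survival::coxph(survival::Surv(times, events) ~ X,
                         ties = "breslow",
                         control = survival::coxph.control(eps = 1e-9,
                                                           iter.max = 50L))
  beta <- unname(stats::coef(fit))
  se <- sqrt(diag(fit$var))
  converged <- is.finite(fit$loglik[2L]) && all(is.finite(beta)) &&
    all(abs(beta) <= 20)
  if (!converged) {
    warning("possible monotone likelihood (separation); ",
            "coefficients capped at |beta| = 20")
    beta <- pmin(pmax(beta, -20), 20)
  }
  z <- beta / se
  structure(list(coef = stats::setNames(beta, colnames(X)),
                 se = stats::setNames(se, colnames(X)),
                 hr = exp(beta),
                 ci_lower = exp(beta - 1.96 * se),
                 ci_upper = exp(beta + 1.96 * se),
                 z = z, p = 2 * stats::pnorm(-abs(z)),
                 loglik = fit$loglik, converged = converged,
                 iterations = fit$iter, n = fit$n, n_event = fit$nevent),
            class = "cox_fit")
}

# one-hot encoding with lexicographically-first reference level
encode_covariates <- function(covariates, n) {
  if (is.null(dim(covariates)) && !is.data.frame(covariates)) {
    covariates <- data.frame(x = covariates)
  }
  covariates <- as.data.frame(covariates, stringsAsFactors = FALSE)
  stopifnot(nrow(covariates) == n)
  cols <- lapply(seq_along(covariates), function(j) {
    v <- covariates[[j]]
    nm <- colnames(covariates)[j]
    if (is.numeric(v)) {
      if (anyNA(v) || any(!is.finite(v))) stop("non-finite covariate: ", nm)
      m <- matrix(v, ncol = 1L, dimnames = list(NULL, nm))
    } else {
      f <- factor(v, levels = sort(unique(as.character(v))))
      m <- stats::model.matrix(~ f)[, -1L, drop = FALSE]
      colnames(m) <- paste0(nm, levels(f)[-1L])
    }
    m
  })
  do.call(cbind, cols)
}

#' Univariate Cox screen of candidate signature genes
#'
#' Fits one Cox model per gene on its z-scored expression; genes are kept
#' when the Wald p-value is below `alpha`. Genes whose fit fails or does not
#' converge are flagged and never kept.
#'
#' @param expr Genes x samples matrix.
#' @param clinical Clinical table aligned to `expr` (same samples, same
#'   order).
#' @param gene_ids Genes to screen.
#' @param alpha Wald significance threshold.
#' @return `data.frame`: `gene`, `coef`, `hr`, `ci_lower`, `ci_upper`, `p`,
#'   `converged`, `keep`.
#' @export
cox_screen <- function(expr, clinical, gene_ids, alpha = 0.05) {
  miss <- setdiff(gene_ids, rownames(expr))
  if (length(miss)) stop("gene(s) absent: ",
                         paste(utils::head(miss, 5L), collapse = ", "))
  stopifnot(identical(colnames(expr), clinical$sample_id))
  rows <- lapply(gene_ids, function(g) {
    x <- expr[g, ]
    fit <- tryCatch(suppressWarnings(
      cox_fit(clinical$os_time, clinical$os_event, scale(x)[, 1L])),
      error = function(e) NULL)
    if (is.null(fit)) {
      data.frame(gene = g, coef = NA_real_, hr = NA_real_,
                 ci_lower = NA_real_, ci_upper = NA_real_, p = NA_real_,
                 converged = FALSE, keep = FALSE)
    } else {
      data.frame(gene = g, coef = fit$coef[[1L]], hr = fit$hr[[1L]],
                 ci_lower = fit$ci_lower[[1L]], ci_upper = fit$ci_upper[[1L]],
                 p = fit$p[[1L]], converged = fit$converged,
                 keep = fit$converged && fit$p[[1L]] < alpha)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# standardized two-group log-rank statistic (O1 - E1)/sqrt(V) for
# group1 = {low}; direct hypergeometric accumulation over event times
logrank_z <- function(times, events, in_low) {
  ord <- order(times)
  t_s <- times[ord]; e_s <- events[ord]; g_s <- in_low[ord]
  n <- length(t_s)
  ev_times <- unique(t_s[e_s == 1])
  O1 <- E1 <- V <- 0
  for (tt in ev_times) {
    at_risk <- t_s >= tt
    n_t <- sum(at_risk)
    n1_t <- sum(at_risk & g_s)
    d_t <- sum(e_s == 1 & t_s == tt)
    d1_t <- sum(e_s == 1 & t_s == tt & g_s)
    O1 <- O1 + d1_t
    E1 <- E1 + d_t * n1_t / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  c(o_minus_e = O1 - E1, var = V,
    z = if (V > 0) (O1 - E1) / sqrt(V) else 0)
}

#' Maximally selected rank-statistic cutpoint
#'
#' Evaluates the standardized two-group log-rank statistic
#' `z(c) = (O1 - E1)/sqrt(V)` at every admissible observed score value `c`
#' (both groups at least `ceiling(minprop * n)`), and returns the cutpoint
#' maximizing `|z|` (ties toward the smaller value). The low group is
#' `score <= c`. No p-value is attached: the maximum over cutpoints is
#' heavily selection-biased and downstream survival contrasts on the
#' dichotomized groups are descriptive.
#'
#' @param score Numeric score per subject.
#' @param times,events Survival input.
#' @param minprop Minimum fraction of subjects in each group.
#' @return List (class `cutpoint_result`): `cutpoint`, `statistic` (max
#'   `|z|`), `candidates`, `z` (per candidate, signed), `minprop`,
#'   `n_low`, `n_high`.
#' @export
max_stat_cutpoint <- function(score, times, events, minprop = 0.1) {
  check_surv(times, events)
  stopifnot(length(score) == length(times))
  n <- length(score)
  min_n <- ceiling(minprop * n)
  cand <- sort(unique(score))
  n_low <- vapply(cand, function(c) sum(score <= c), 0L)
  ok <- n_low >= min_n & n_low <= n - min_n
  cand <- cand[ok]
  if (length(cand) < 1L) stop("no admissible cutpoint at minprop = ", minprop)
  # one pass over event times, cumulative in score order across candidates
  ord <- order(score)
  t_o <- times[ord]; e_o <- events[ord]; s_o <- score[ord]
  idx_c <- vapply(cand, function(c) sum(s_o <= c), 0L)
  ev_times <- sort(unique(times[events == 1]))
  m <- length(cand)
  O1 <- E1 <- V <- numeric(m)
  for (tt in ev_times) {
    at_risk <- t_o >= tt
    ev_here <- e_o == 1 & t_o == tt
    n_t <- sum(at_risk); d_t <- sum(ev_here)
    n1 <- cumsum(at_risk)[idx_c]
    d1 <- cumsum(ev_here)[idx_c]
    O1 <- O1 + d1
    E1 <- E1 + d_t * n1 / n_t
    if (n_t > 1) {
      V <- V + d_t * (n1 / n_t) * (1 - n1 / n_t) * (n_t - d_t) / (n_t - 1)
    }
  }
  z <- ifelse(V > 0, (O1 - E1) / sqrt(V), 0)
  best <- which.max(abs(z))              # first max -> smaller cutpoint
  cstar <- cand[best]
  structure(list(cutpoint = cstar, statistic = abs(z[best]),
                 candidates = cand, z = z, minprop = minprop,
                 n_low = sum(score <= cstar), n_high = sum(score > cstar)),
            class = "cutpoint_result")
}
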