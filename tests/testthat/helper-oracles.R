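# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (full running-sum vectors, exhaustive enumeration, grid
# search) kept separate from the package's own code paths.

# ssGSEA by materializing the full running-sum vectors, position by position
brute_ssgsea_es <- function(values, gene_ids, set, alpha = 0.25) {
  ord <- order(-values, gene_ids)
  genes_sorted <- gene_ids[ord]
  N <- length(gene_ids)
  z <- N:1                                    # rank weight at each position
  in_set <- genes_sorted %in% set
  denom_in <- sum((z[in_set])^alpha)
  es <- 0
  p_in_run <- 0; p_out_run <- 0
  for (i in seq_len(N)) {
    if (in_set[i]) p_in_run <- p_in_run + z[i]^alpha / denom_in
    else p_out_run <- p_out_run + 1 / (N - sum(in_set))
    es <- es + (p_in_run - p_out_run)
  }
  es
}

# BH step-up straight from the definition
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- p[ord] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(ord)]
}

# two-sided Fisher p by enumerating every table with the observed margins
brute_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  a_vals <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- stats::dhyper(a_vals, c1, n - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Breslow partial log-likelihood for a single covariate (no ties assumed
# away: exact Breslow handling of tied event times)
breslow_loglik <- function(beta, times, events, x) {
  eta <- beta * x
  ll <- 0
  for (tt in unique(times[events == 1])) {
    ev <- which(events == 1 & times == tt)
    risk <- which(times >= tt)
    ll <- ll + sum(eta[ev]) - length(ev) * log(sum(exp(eta[risk])))
  }
  ll
}

grid_search_cox <- function(times, events, x, lo = -5, hi = 5, tol = 1e-3) {
  grid <- seq(lo, hi, by = tol)
  ll <- vapply(grid, breslow_loglik, 0, times = times, events = events, x = x)
  grid[which.max(ll)]
}

# hypergeometric upper tail by direct summation
brute_hyper_tail <- function(k, N, K, n) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# small, fast cohort for unit tests (full structure, reduced sizes)
small_params <- function(seed = 1L, ...) {
  defaults <- list(n_samples = 120L, n_deg = 30L, n_background = 80L,
                   markers_per_cell_type = 5L, seed = seed)
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_params, args)
}
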