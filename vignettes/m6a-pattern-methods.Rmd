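---
title: "Methods: m6A modification-pattern analysis on synthetic cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: m6A modification-pattern analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

`m6Apattern` re-implements, as a tested pipeline, the analysis strategy used
to characterize N6-methyladenosine (m6A) modification patterns in gastric
cancer expression cohorts: consensus clustering of the 21 m6A regulator
genes (8 writers, 2 erasers, 11 readers), ssGSEA quantification of
tumor-microenvironment (TME) cell infiltration, derivation of
phenotype-related genes, a PCA-based per-sample score (the m6A score),
survival dichotomization by maximally selected rank statistics, and
association of the score with mutation burden and immunotherapy response.
Because the original cohorts are external accessions, the package ships a
synthetic-cohort generator with recorded ground truth; every stage is
validated by recovery of that truth, by hand-worked fixtures, and by
independent brute-force oracles.

## The synthetic cohort generator

`simulate_cohort()` draws an ACRG-like cohort whose defaults are fixed once
and act as the package's study conditions:

* **Latent structure.** Each of 300 samples carries a latent pattern label
  (A/B/C with probabilities 0.37/0.33/0.30) and a latent score
  `L = mu(label) + N(0, 0.25)` with `mu(A) = 1, mu(C) = 0, mu(B) = -1`. The
  ordering A > C > B mirrors the biological finding that the
  stromal/immune-excluded pattern scores highest and the inflamed pattern
  lowest.
* **Regulator genes.** 21 genes receive cluster-template means separated by
  `delta * sigma` (defaults `delta = 1.5`, `sigma = 1`, log2 scale). The
  templates are permutations of `(1, 0, -1)` assigned in **balanced**
  proportions over the six permutations, so the three patterns are
  exchangeable: no two patterns are a priori more similar than any other
  pair, and with 21 genes the three inter-centroid distances are exactly
  equal. An unbalanced (i.i.d.) assignment would give each simulated cohort
  an arbitrary "closest pair" of patterns — an asymmetry that is an artifact
  of the template draw, not a property being studied.
* **Phenotype-related (DEG) block.** 200 genes follow the latent-score
  cluster means (`delta * sigma * mu(label)`, each gene randomly up- or
  down-regulated). This makes every pairwise cluster contrast non-null —
  required for reading "overlap genes" as an intersection of pairwise DEG
  sets — and gives the block a leading principal component aligned with the
  latent score, as a transcriptional program tracking a phenotype would
  have.
* **Cell-type markers.** 8 cell types (3 innate, 2 stromal, 3 adaptive),
  15 markers each, with label-specific abundance shifts: pattern A high in
  innate + stromal (immune-excluded), B high in adaptive (inflamed), C low.
  All per-type abundances are distinct across labels so enrichment-ordering
  checks are strict.
* **Survival.** Exponential event times with hazard
  `0.01 * exp(0.7 * L)` per month, censored uniformly on (0, 120]. The
  constant baseline hazard gives closed-form Kaplan-Meier checks.
* **Mutation burden.** Negative-binomial counts with mean
  `exp(log(10) - 0.8 * L)` and dispersion 2 — a median of roughly ten
  nonsilent mutations, anti-correlated with the score, materialized as
  MAF-lite records (plus a few Silent records to exercise class filtering).
* **ICB response.** Bernoulli with `P = plogis(-0.4 - 1.0 * L)`, i.e. about
  a 40% response rate at the score midpoint, declining with the score.

Each data layer (labels, expression, survival, mutations, response) has its
own RNG stream derived from the master seed, so toggling one layer leaves
the others bit-identical. What the generator does **not** emulate: realistic
gene-gene correlation beyond block structure, batch effects, copy-number
events, or array/RNA-seq platform mixtures. Passing recovery tests therefore
demonstrates correctness of the algorithms under the stated model, not
robustness to those real-data complications.

## Consensus clustering and the choice of k

`run_consensus()` follows the resampling-consensus procedure: per resample,
`p_item = 0.8` of samples are drawn without replacement and clustered by
agglomerative clustering with average linkage on `1 - Pearson` distance of
per-gene z-scored regulator profiles, cut at `k` (k-means is available
behind a flag). The consensus matrix is the ratio of co-clustering to
co-sampling counts; pairs never co-sampled contribute 0 with a warning
(with `B >= 100` and `p_item = 0.8` every pair is co-sampled with
overwhelming probability). Production runs use `B = 1000` repetitions;
tests and the bundled analyses use `B = 100` for speed, which already
drives the Monte-Carlo error of consensus entries below ~0.05.

`k` is chosen by minimizing the proportion of ambiguous clustering
(PAC; the consensus-CDF mass between 0.1 and 0.9), ties toward the smaller
k; the delta-area statistic is reported for audit. One subtlety motivated a
design choice: with a deterministic base clusterer, a forced merge of two
genuinely distinct clusters at too-small k can be perfectly *stable* — the
same two clusters merge in every resample — so item resampling alone gives
PAC = 0 at k below the truth. `run_consensus()` therefore also supports
feature subsampling (`p_feature`, as in the ConsensusClusterPlus
`pFeature` argument). The pipeline default `p_feature = 0.8` perturbs the
regulator panel per resample, which makes a wrong-k merge unstable and
visible to PAC while leaving the correct-k solution unaffected. The
standalone default remains `p_feature = 1`, preserving the exact
`p_item = 1` degeneracy (all consensus entries in {0, 1}).

## ssGSEA

`ssgsea_scores()` implements the single-sample running-sum enrichment
score. Per sample, the N genes are ranked by expression (descending, ties
broken lexicographically by gene id for determinism); position i carries
weight `z = N - i + 1`. For a set S,

    ES(S) = sum_i [ P_in(i) - P_out(i) ],

with `P_in` the alpha-weighted (`alpha = 0.25`) cumulative fraction of
set-gene weight through position i and `P_out` the cumulative fraction of
non-set genes. Integer rank positions rather than raw expression are used
as weights — the score is then invariant to any strictly monotone
per-sample transform, which stabilizes behavior across normalization
choices and platforms. The summed (not maximal) deviation is used, per the
original ssGSEA definition. Normalization divides the whole score matrix by
its global max - min (per-set normalization available by flag). Sets
overlapping the matrix in fewer than 2 genes are dropped with a warning; a
set covering every gene is an error (`P_out` undefined).

## Phenotype-related genes

Differential expression between patterns uses a moderated two-sample t:
pooled variances are shrunk toward a prior,
`s2_post = (d0 s0^2 + d_g s2_g) / (d0 + d_g)`, with `(d0, s0^2)` estimated
by method of moments on the log sample variances (the standard
empirical-Bayes moderated-t estimator; the package's estimate is
cross-checked against limma in the test suite but computed independently).
If the moment equation has no positive solution — which is expected when
genes are near-homoscedastic, as in the synthetic cohorts — `d0 = Inf`
(full shrinkage) is used and noted. P-values use `d0 + d_g` degrees of
freedom and are BH-adjusted.

"Phenotype-related genes" are the **intersection** of the three pairwise
DEG sets (A-vs-B, A-vs-C, B-vs-C) at adjusted p < 0.001; a union mode is
available since the published description ("the overlap genes were
extracted") is ambiguous. No fold-change filter is applied — the published
criterion is the adjusted p-value alone. Over-representation of a gene list
in user-supplied sets uses the exact hypergeometric tail with BH control.

## Survival machinery

Kaplan-Meier, log-rank and Cox models are delegated to the `survival`
package (product-limit with Greenwood variance; hypergeometric expected
events; Breslow tie handling in `coxph`, Newton iteration to a 1e-9 score
tolerance, max 50 iterations). Breslow rather than Efron ties: simulated
continuous times make ties rare, and the hand-computable Breslow likelihood
doubles as the grid-search oracle in tests. Monotone likelihood
(separation) is flagged: coefficients are capped at |beta| = 20 and the fit
marked non-converged; screened genes with such fits are never kept.
Categorical covariates are one-hot encoded against the lexicographically
first level.

The maximally selected rank-statistic cutpoint evaluates the standardized
two-group log-rank statistic `z(c) = (O1 - E1)/sqrt(V)` at every observed
score value c whose low group (`score <= c`) and high group both contain at
least `ceiling(minprop * n)` subjects (`minprop = 0.1`), and returns the
argmax of |z| (ties toward the smaller c). Candidates with zero log-rank
variance contribute z = 0. **No p-value is attached** to the maximum: the
selection effect inflates |z| far beyond its nominal distribution (the test
suite demonstrates this under the null), so downstream KM/log-rank contrasts
on the dichotomized groups are reported as descriptive.

## The m6A score

Signature genes are z-scored across samples; the samples-by-genes matrix is
decomposed by SVD (PCA on the correlation scale — the cohorts a user would
mix span platforms, so unit-variance genes are the defensible default), and
the score is the per-sample sum of the first two principal-component
projections. Principal-component signs are arbitrary, so each component is
oriented deterministically (its largest-|loading| gene loads positively),
and — because a global flip inverts the *meaning* of high vs low score —
the pipeline can additionally orient the final score to correlate
positively with a user-chosen stromal signature (`orient_to_set`),
reproducing the "high score = stromal / immune-excluded" reading. The
bundled analyses orient to a stromal marker set. The per-sample sum
`PC1_s + PC2_s` is the reading of the published score formula in which each
component score is already a loading-weighted sum over signature genes.

Association statistics around the score use mid-rank Spearman correlation
(t approximation, n - 2 df), tie-corrected Kruskal-Wallis, Mann-Whitney U,
the probability-mass two-sided Fisher exact test (odds ratio reported as
the sample ad/bc with a 0.5 continuity add when a cell is zero), and the
rank-based AUC.

## Mutation burden

TMB is the per-sample count of nonsilent records (Missense, Nonsense,
Frame_Shift_Ins/Del, Splice_Site, In_Frame_Ins/Del); counts rather than
per-megabase rates, since panel size is unavailable in MAF-lite input.
Mutation frequency is the fraction of distinct mutated samples, and
pairwise co-occurrence/exclusivity uses Fisher tests on sample-level 2x2
tables with BH control.

## Numerical conventions and degenerate inputs

* Duplicate expression rows are mean-collapsed at load; missing values are
  a load error (silent imputation would distort rank-based ssGSEA).
* FPKM-to-TPM: per-sample scaling to one million; all-zero samples error.
* Zero-variance genes: error in clustering features and the score (dropped
  only where a contract says so, e.g. z-score signatures warn and drop).
* Expression ties in ssGSEA break lexicographically; PAC ties and cutpoint
  ties break toward the smaller value; `which.min`/`which.max` firsts make
  every selection deterministic.
* All pipeline randomness flows from one master seed through per-stage
  derived seeds; `report.json` is byte-identical across reruns.

## Problem sizes used by the bundled checks

The test-suite and acceptance runs use the generator defaults (n = 300,
1141 genes) with `B = 100` consensus repetitions over k = 2..6, 10
independent cohorts for k-selection and clustering recovery, 200
replicates for Cox coefficient recovery (n = 500, true log HR = log 2),
10 replicates for cutpoint recovery (n = 500, hazard step at the 60th
percentile), and 20-50 replicates for the global-null error-control
simulations. These sizes keep each Monte-Carlo standard error comfortably
below the margins being asserted.

## Known limitations

* The consensus base clusterer, distance, linkage, subsampling fractions
  and the PAC rule are declared defaults; the published analysis does not
  state its settings, so agreement with it is structural, not numerical.
* Cohort-specific published outputs (cluster sizes, the 718-gene signature,
  the 0.0291 cutoff, external-cohort hazard ratios) depend on external
  accessions and are intentionally out of scope.
* Efron ties, time-dependent covariates, competing risks, distance
  correlation and selection-bias-corrected cutpoint inference are not
  implemented.
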