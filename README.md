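# m6Apattern

Tumor cohorts differ in how their N6-methyladenosine (m6A) RNA-modification
machinery — 21 regulator genes comprising writers, erasers and readers — is
expressed, and those differences track the immune character of the tumor
microenvironment (TME), patient survival, mutation burden and response to
immune-checkpoint blockade. `m6Apattern` is an R package plus a scripted
analysis that implements this pattern-analysis workflow end to end for
gastric-cancer-like expression cohorts, and validates every stage on
synthetic cohorts with known ground truth.

The pipeline:

1. **Consensus clustering** of samples on the 21 regulators: agglomerative
   clustering (1 − Pearson distance, average linkage) over resampled
   subsets (`p_item`, optionally `p_feature`), consensus matrix
   `M_ij = co-cluster / co-sampled`, and data-driven selection of the
   cluster number by minimum PAC (proportion of ambiguous clustering,
   `F(0.9) − F(0.1)` of the consensus CDF).
2. **TME quantification** by ssGSEA: per sample, genes are ranked and each
   marker set S scored by the summed running-sum deviation
   `ES(S) = Σ_i [P_in(i) − P_out(i)]` with rank weights `z^α`, `α = 0.25`.
3. **Phenotype-related genes**: empirical-Bayes moderated t between each
   pair of patterns (variance shrinkage
   `s̃² = (d₀s₀² + d_g s²_g)/(d₀ + d_g)`), BH adjustment, intersection of
   the pairwise DEG sets at adjusted p < 0.001.
4. **m6A score**: univariate Cox screen of the phenotype genes, then PCA of
   the z-scored signature matrix with `m6Ascore_s = PC1_s + PC2_s`
   (deterministic sign orientation, optional stromal re-orientation).
5. **Survival dichotomization** at the maximally selected rank statistic
   (max over admissible cutpoints of the standardized log-rank
   `z(c) = (O₁ − E₁)/√V`, `minprop = 0.1`), then Kaplan–Meier, log-rank and
   uni-/multivariable Cox summaries.
6. **Associations**: Spearman correlation of the score with tumor mutation
   burden (nonsilent counts from MAF-lite records), per-gene mutation
   frequencies and pairwise co-occurrence Fisher tests, and
   checkpoint-blockade response (rank AUC, response-rate Fisher contrast).

A synthetic-cohort generator (`simulate_cohort()`) emulates an ACRG-like
cohort — 300 samples, 3 latent modification patterns imprinted on the
regulators, a 200-gene phenotype block, immune/stromal marker structure,
exponential survival tied to a latent score, negative-binomial TMB and
Bernoulli ICB response — and records the generating truth so that cluster
recovery, score fidelity, coefficient bias and error control are all
testable offline.

## Worked example

The scripted analysis under `analysis/` runs the whole workflow on the
default synthetic cohort (`Rscript analysis/01_simulate.R` … `06_full_report.R`),
writing tables under `results/`. In code:

```r
library(m6Apattern)

co  <- simulate_cohort(sim_params(seed = 1))
cfg <- pipeline_config(expression = co$expr, clinical = co$clinical,
                       regulators = co$regulator_ids,
                       markers_gmt = co$cell_marker_sets,
                       mutations  = co$mutations,
                       consensus_B = 100, k_min = 2, k_max = 6,
                       orient_to_set = "stromal_cell_04", seed = 1)
report <- run_pipeline(cfg)
```

On this cohort the pipeline prints (via `analysis/02` and `analysis/05`):

```
PAC by k:
  k    pac
  2 0.3729
  3 0.0000
  4 0.0121
  5 0.0293
  6 0.0541
chosen k: 3
ARI vs generating labels: 1

log-rank chi-square = 47.36 (p = 5.91e-12)
  5-year survival, low m6Ascore: 64.5%
  5-year survival, high m6Ascore: 32.6%
HR high vs low: 3.20 (95% CI 2.25-4.53)
Spearman rho(m6Ascore, TMB) = -0.555 (p = 1.25e-25)
AUC of low m6Ascore for ICB response: 0.727
response rate low/high: 52% / 19% (Fisher p = 5.72e-09)
```

Reading: the consensus scan is unambiguous only at k = 3 (PAC 0), and the
recovered patterns match the generating labels exactly. The high-score
group — oriented so that high means stromal/immune-excluded — has about a
threefold death hazard, half the 5-year survival, lower mutation burden
(negative Spearman rho) and a markedly lower response rate to checkpoint
blockade, which is the qualitative behavior the score is designed to
capture.

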