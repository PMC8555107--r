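---
title: "Serum peptidome biomarker discovery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Serum peptidome biomarker discovery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Workers who manufacture or handle carbon nanotubes and nanofibers (CNT/F)
inhale a high-aspect nanomaterial whose long-term health effects are a
standing occupational-health concern. Classical protein markers in blood
have proven insensitive to the sub-symptomatic effects seen in animal
models. The serum peptidome — the complement of endogenous peptide
fragments below ~8 kDa circulating in blood — responds strongly to
pulmonary CNT/F insult and is measurable by label-free,
ion-mobility-enabled mass spectrometry.

`peptidomeDx` implements a discovery pipeline that asks: among thousands
of serum peptide ion features quantified across a stratified cohort of
High (> 0.5 µg/m³ inhalable elemental carbon) and Low (< 0.13 µg/m³, the
assay limit of quantification) exposure workers, which peptides track
personal breathing-zone exposure well enough to serve as biomarkers, and
how well does a compact panel of them classify exposure group?

## Pipeline model

The stages, each exposed as package functions and orchestrated by
`run_pipeline()`:

1. **Ion-event alignment** (`cluster_ion_events()`). Per-sample ion
   events are clustered across biological replicates within ± 2 min
   retention time, ± 4 ion-mobility drift bins, and ± 6 ppm
   charge-reduced mass (MH⁺). The aligner is greedy and
   intensity-seeded: events are processed in descending intensity, each
   joining the cluster whose intensity-weighted running centroid lies
   within all three windows (smallest mass difference breaks ties), or
   founding a new cluster. The underlying acquisition software is
   proprietary and its algorithm unpublished; greedy intensity-seeded
   matching was chosen because it is deterministic, fast, and provably
   equal to the exhaustive within-tolerance connected components whenever
   clusters are separated by more than twice each tolerance — a property
   the test suite checks against a brute-force oracle. Whether the
   original tool aligned all-vs-all or to a reference run is unknown;
   global all-vs-all clustering is this package's declared choice.

2. **Preprocessing** (`preprocess()`). Reproducibility filtering keeps
   peptides detected in ≥ 50% (then ≥ 75%) of workers *per group* — the
   stricter of the two plausible readings ("per group" vs "of workers"),
   switchable via `rule = "either"`. Columns are median centered
   multiplicatively to the log-space median of the column medians
   (equivalently: additive median centering in log2 space, which
   preserves the positivity the log2 transform needs). Missing cells are
   left-censored — ions below the intensity limit of quantification
   (LOQ) go undetected — and are imputed *at* the LOQ, not LOQ/2 or by a
   model-based method, because censoring at the quantification limit
   makes the LOQ itself the least-assumptive value. Values are then
   log2-transformed and standardized per peptide as fold difference from
   the Low-group mean. Whether centering preceded or followed imputation
   in the original workflow is unstated; the default here is center →
   impute → log2 (imputing first would let the LOQ constant distort
   column medians), and the order is switchable.

3. **Univariate screen** (`row_t_test()`). Pooled-variance (Student)
   two-sample t-tests per peptide with Benjamini–Hochberg control at a
   5% false discovery rate. Zero-variance degenerate rows resolve to
   p = 1 (equal means) or p = 0 (unequal) rather than erroring.

4. **Model voting** (`aicc_table()`, `vote_models()`). Candidate linear
   models — every base exposure construct (single log10 metrics, the
   two-metric and three-metric composites `logInhResEC`/`logSumExp`)
   crossed with covariate subsets (SCIP serum-inflammation measures,
   age, exposure duration, sex, solvent history) — are fit to every
   screened peptide by OLS and scored with the small-sample Akaike
   criterion, AICc = n·ln(RSS/n) + 2k + 2k(k+1)/(n−k−1), where k counts
   coefficients, intercept, and residual variance. Each peptide votes
   for its lowest-AICc model; a model's count is tested against "random"
   with a one-sample z-test whose null mean and sd are the empirical
   moments of the counts across all models (the simplest reading of
   significance-from-random), one-sided upper tail, BH-corrected within
   the model family. One-sided p-values are the default because the
   published q-value for the fifth-ranked model (q = 0.0029 at Z = 3.84,
   family of 237) is numerically consistent only with one-sided tails —
   the package reproduces that number exactly in its tests. Exact AICc
   ties split a peptide's vote equally among the tied models, which
   keeps counts summing to the peptide total, is invariant to peptide
   order, and yields uniform counts (all Z = 0) in the fully degenerate
   all-tied case. With `delta > 0`, all models within `delta` AICc units
   co-win and counts may overlap, mirroring published per-model counts
   whose sum exceeds the screened set. The published family size (237)
   is not exactly reconstructible from its description; the default
   space enumerates 5 bases × covariate subsets of size ≤ 2 from 10
   covariates = 280 models, and the correction family size `m_family` is
   an independent parameter. Models rendered rank-deficient by a
   particular cohort (e.g. a history flag constant across its 24
   workers) are not estimable and sit out the vote; the manifest records
   how many.

5. **Correlation filter** (`correlation_filter()`). Adjusted R² of each
   screened peptide against the selected models, tiered at ≥ 0.4
   (moderate) and ≥ 0.7 (strong). The "common" set intersects the
   strong sets of the *best-voted model and its vote-significant
   covariate extensions* (predictor supersets) — not of every
   significant model. Intersecting with non-nested rivals (e.g. a
   single-metric base) would discard genuinely exposure-linked peptides
   merely because a weaker exposure construct correlates less; the
   nested intersection is exactly the published three-way overlap
   (composite, + IL6, + IL6 + age) and guards against orthogonal
   covariates inflating R². "Shapiro R²" appears in one figure caption
   of the source workflow; adjusted R² (as in its Methods) is what is
   implemented.

6. **Discriminant refinement** (`fit_plsda()`, `vip_scores()`,
   `cross_validate()`, `validate_split()`, `pca_variance()`). PLS-DA on
   the common peptides with the class coded 0/1 and centered, features
   autoscaled, two components by default (the published analysis plots a
   2-D score projection but does not state its component count). With a
   single response column the NIPALS iteration converges on its first
   pass, so each component is computed in closed form (w ∝ X'y); the
   test suite confirms the first weight equals the dominant eigenvector
   of X'yy'X and that the fit matches an independent PLS-DA
   implementation (mixOmics). Variable importance in projection:
   VIP_j = √(p·Σ_a ssy_a (w_aj/‖w_a‖)² / Σ_a ssy_a), so ΣVIP² = p;
   peptides with VIP ≥ 1.0 are selected and the top five form the
   compact model. Cross-validation (leave-one-out or Monte-Carlo
   leave-n-out, default 50 repeats holding out 4 of 24) refits the model
   *within each fold, re-estimating centering and scaling from training
   workers only* — the source Methods do not state this, but computing
   scaling on all workers would leak held-out information into Q² and
   invalidate it. Q² = 1 − PRESS/TSS with TSS about training-fold means.
   Class probability is the continuous prediction linearly mapped
   between the coded class values and clipped to [0, 1] — deterministic
   and monotone, chosen because the original "average class
   probabilities" are plotted but never defined. Split-sample validation
   builds the model on a random stratified half of workers and
   classifies the other half across 50 resamplings. Finally,
   unsupervised PCA on the full reproducible matrix checks that group
   separation is a latent property of the data (guarding against
   supervised overfitting), reporting per-component explained-variance
   fractions.

## The synthetic cohort generator

Worker-level data from the motivating study are protected, so
`generate_cohort()`/`generate_peptidome()` produce seeded synthetic
cohorts with the statistical structure the analysis assumes.

**Cohort.** 12 + 12 workers. Exposure metrics are lognormal with
location/scale moment-matched to the published per-group arithmetic
means and standard errors (inhalable EC 8.706 (5.402) vs 0.055 (0.014)
µg/m³; respirable EC 1.564 (0.964) vs 0.017 (0.006); structure count
0.442 (0.310) vs 0.005 (0.002); SEs refer to n = 12): with
cv = sd/mean, σ² = ln(1 + cv²) and µ = ln(mean) − σ²/2. Group
membership is enforced by rejection sampling on inhalable EC (High
> 0.5, Low < 0.13 µg/m³); the raw moment-matched sampler is exported
separately (`rlnorm_matched()`) since truncation shifts the mean.
Demographics, history flags and the five SCIP covariates are drawn from
the published per-group summaries, hence balanced in expectation.

**Peptidome.** 12,000 features in four classes with ground truth
emitted alongside so recovery metrics are computable:

| class | default n | model |
|---|---|---|
| null | 10,909 | baseline + noise |
| responsive | 900 | α + β·(composite exposure) + ε, noise solved from var(βx)(1−r²)/r² for an expected R² of 0.85 |
| top discriminant | 41 | group shift of 10–13 log2 units (3–4 orders of magnitude), sign random |
| nuisance | 150 | linear in serum IL6 induction or age bin, same R² calibration |

Planted effect signs are random: serum peptides respond in both
directions, and balanced signs keep column medians free of a group-level
bias that would otherwise propagate through median centering into every
null peptide and destroy type-I error control (the suite verifies a 5%
screen rejects 5% ± 1% of planted nulls). The less-abundant group's mean
for each top-discriminant peptide is pinned 3 log2 units above the LOQ
so both groups stay quantifiable. Censoring is a hard threshold: any
cell whose latent intensity falls below the LOQ (2⁶ by default, with
baselines near 2¹⁴) is recorded missing. A logistic detection curve was
considered and rejected because a stochastic detection model violates
the invariant that every masked cell's latent value lies below the LOQ;
hard thresholding is its zero-width limit. A
missing-completely-at-random mode exists for null testing.

**Free parameters.** The within-group intensity noise of real peptides
is unreported, so `noise_sd` (null and top-discriminant peptides) is a
free parameter. Its default, 0.15 log2 units (~11% CV), emulates the
near-unity within-group consistency the motivating study observed for
its top ions — its top-5 model's cross-validated Q² of 0.99916 implies
residual noise at about this scale, and larger defaults (0.3–0.5 log2)
contradict that observed consistency. With this default the synthetic
analogue attains accuracy 1.0 and Q² ≥ 0.9994 across seeds.

**What the generator does not emulate.** Raw spectra, chromatography,
isotope patterns and charge states; correlated peptide blocks from
shared parent proteins; batch and acquisition-order effects; non-linear
exposure–response; heavy-tailed or peptide-specific noise. Passing
recovery tests therefore demonstrates that the pipeline's inference
machinery is correct under its own assumptions, not that real serum
data satisfy those assumptions.

## Tunable parameters that matter

| parameter | default | units | rationale |
|---|---|---|---|
| `rt_tol`, `drift_tol`, `mass_tol_ppm` | 2 / 4 / 6 | min / bins / ppm | the published alignment windows |
| `min_frac` tiers | 0.5, 0.75 | fraction per group | reproducibility then power (≥ 9 of 12) |
| `fdr` | 0.05 | — | published 5% FDR screen |
| correlation `thresholds` | 0.4 / 0.7 | adjusted R² | published moderate/strong tiers |
| `vip_cutoff`, `top_k` | 1.0, 5 | — | conventional VIP cutoff; compact panel size |
| `n_components` | 2 | — | 2-D score projection; configurable |
| `cv_repeats`, `cv_holdout` | 50, 4 | — | 50 published resamplings; 4 of 24 leaves ≥ 8 per class in training |
| `m_family` | n models | — | set to 237 to mirror the published family |

## Numerical choices and degenerate inputs

- AICc drops the additive normal-likelihood constants (n·ln 2π + n);
  tests verify agreement with `stats::logLik` after removing them, at
  1e-9.
- RSS at rounding level (≤ 1e-12 × TSS) is treated as a perfect fit and
  flagged with an −Inf AICc sentinel rather than feeding `log(≈0)`
  noise into votes.
- Zero pooled variance in the t-test, all-identical Kruskal–Wallis input
  (tie-correction denominator zero), constant-y adjusted R² (defined as
  0), and zero-variance PLS features (dropped with a warning) are all
  resolved explicitly.
- Cross-validation folds whose training set loses a class are skipped
  and counted in the report.
- All randomness flows from one root seed, split per stage with a
  fixed affine map kept below 2³¹ in double arithmetic.

## Problem sizes used by the test suite

The suite generates data at the default scale (12,000 × 24) for the
end-to-end recovery checks — 10 seeds for the cross-validation bound, 20
seeds for vote recovery, VIP recall, and error-free split validation —
and reduced scales (hundreds to a few thousand features) for unit-level
properties, sizes chosen so the whole suite completes in about a minute
on one core while keeping every Monte-Carlo margin comfortable.

## Known limitations

- The greedy aligner can, in principle, differ from single-linkage
  components when true clusters are closer than twice a tolerance;
  ordering by intensity makes the behavior deterministic but not
  globally optimal.
- The 237-model family and the original power calculation's variance
  assumptions are not reconstructible; both are exposed as parameters
  instead.
- Q² on a 24-worker cohort has high seed-to-seed variance for weak
  signals; the near-unity values here reflect the planted effect sizes,
  not a general property of the method.
- Imputation at the LOQ understates uncertainty for heavily censored
  peptides; no censored-likelihood model is fit.
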