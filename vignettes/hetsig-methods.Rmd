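---
title: "Methods: outcome classifiers and homogeneity analysis for expression cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: outcome classifiers and homogeneity analysis for expression cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hetsig)
```

## The problem

Cohorts of men managed by watchful waiting for localized prostate cancer
split into two extreme outcome classes: *lethal* (death from prostate cancer
during follow-up) and *indolent* (at least ten years of survival without
progression). Given log-scale expression profiles of a few thousand genes
per tumour sample plus clinical covariates (age, grouped Gleason score, ERG
rearrangement status), two questions arise:

1. Can a molecular or combined molecular/clinical classifier separate lethal
   from indolent disease, evaluated *fairly* — i.e. with every data-driven
   choice, above all gene selection, made strictly inside training data?
2. If classifiers disappoint, is the cause molecular heterogeneity of the
   outcome classes — several distinct expression programs leading to
   lethality — rather than absence of signal?

`hetsig` implements both analyses as reusable, seeded pipelines, together
with a synthetic-cohort generator that reproduces the statistical structure
the analyses assume, so that every stage is testable without any external
download.

## The evaluation protocol

The cohort (excluded outcomes dropped) is split once, stratified by outcome,
into a Learning and a Validation set (`split_learning_validation()`; default
fraction 0.5 — no single value is canonical, so it is a configurable
parameter). Within the Learning set, a stratified k-fold cross-validation
(default k = 10) is repeated R times (default 100), giving R·k train/test
partitions (`make_fold_plans()`). For every partition:

* genes are selected on the training slice only (`select_features_in_fold()`),
  either by a per-gene two-sided t-test threshold (p < 0.01 or 0.001 are the
  canonical choices) or by a stepwise rule: genes sorted by p are added one
  at a time and each candidate set size is scored by inner stratified
  cross-validated AUC (default 5 inner folds) on the training slice; the
  smallest set attaining the maximal inner AUC wins ("best AUC with the
  fewest gene predictors");
* a classifier is trained on the training slice and scores the held-out
  fold; the fold AUC is recorded (Mann–Whitney form: concordant pairs plus
  half ties over all lethal × indolent pairs).

Per-repetition means are aggregated into a grand mean per model
(`run_cv()`); the best model (maximal grand mean, ties to fewer genes, then
a documented family order) is refit on the full Learning set and evaluated
once on the Validation set (`validate_final()`), with two labelled
confidence intervals: a stratified bootstrap percentile interval over
validation resamples (default 2000), and, for gene-using models, the
percentile interval of the repetition-level CV AUC distribution.

The anti-leakage contract is structural: `select_features_in_fold()` receives
only the training slice, so it *cannot* read test samples. A deliberately
leaky variant (`run_cv(leaky = TRUE)`, selection once on all samples) is
provided purely to demonstrate selection bias: on label-permuted data the
honest pipeline stays at AUC ≈ 0.5 while the leaky variant inflates far
above it. The package's test suite asserts both.

### Classifier families

All families produce a continuous lethality score (larger ⇒ more lethal) and
freeze any standardisation statistics on training data:

* **DLDA** — diagonal linear discriminant analysis: per-class per-gene means
  with pooled per-gene variances; score
  \(\sum_g [(x_g-\mu_{g,I})^2 - (x_g-\mu_{g,L})^2]/s_g^2\).
* **kNN** — Euclidean k-nearest neighbours (k odd); score is the lethal
  fraction among the k nearest training samples; distance ties break to the
  smaller training-sample index after a stable sort.
* **NTP** — nearest-template prediction: signed ±1 templates from the
  training mean differences of per-gene standardised markers; score is the
  difference of cosine distances to the indolent and lethal templates
  (equivalently twice the cosine similarity to the lethal template). The
  original permutation-based confidence is omitted: only the ranking score
  feeds the AUC.
* **Logistic regression** — ridge-penalised maximum likelihood by IRLS
  (convergence 1e-8, at most 100 iterations, intercept unpenalised; default
  penalty 1e-4). Separation at penalty 0 is detected and triggers a flagged
  refit at the default penalty. Clinical covariates enter as age (linear)
  and reference-coded indicators (references G4_6 and ERG-negative; an
  `unknown` level gets its own indicator rather than silently joining the
  reference).
* **Plugins** — any external learner (e.g. an SVM) enters through a
  train/score function pair in the spec's hyperparameters; the harness
  treats it exactly like a native family.

DLDA, kNN and NTP operate on genes only; mixing clinical fields is done
through logistic regression or a plugin, matching how combined models are
ordinarily reported for this design.

## The homogeneity analysis

Heterogeneity is quantified by silhouette widths over sample–sample
distances (default `one_minus_pearson`; Euclidean selectable — both are
exposed and logged because the choice is not canonical). For sample *i* with
mean within-group distance *a(i)* and mean other-group distance *b(i)*, the
homogeneity score is \(s(i) = (b(i)-a(i))/\max(a(i), b(i))\); samples alone
in their group score 0 by convention. Group averages are graded by the
classical interpretation bands — above 0.70 strong, 0.51–0.70 reasonable,
0.26–0.50 weak, at or below 0.25 none — which agree with both labelled
anchors in the prostate literature (0.71 "strong", 0.34 "weak").

The gene set for the distances is deliberately *overfit*: per-gene t-tests
on the entire cohort with Storey q-values, keeping q < 0.05
(`overfit_signature()`). Overfitting is the point — these are the best
available molecular descriptors of the two groups, so if even they cannot
make the classes look homogeneous, heterogeneity is the parsimonious
explanation. This gene set is never used for classifier evaluation.

Stroma contamination (non-tumour tissue signal) is flagged by
average-linkage hierarchical clustering on 1−Pearson distances over a
stroma signature (typically 47 genes), cut into two clusters; the cluster
with higher mean stroma-gene expression is flagged. Separation strength is
reported as the flagged cluster's average silhouette width and its
structure category: on uncontaminated data the two clusters are arbitrary
and the separation reads weak or none.

### q-values

`compute_q_values()` implements Storey's procedure: the null proportion
\(\pi_0\) is estimated on the λ grid 0.05–0.95 with a cubic smoothing
spline evaluated at the largest λ, and the Benjamini–Hochberg step-up
quantities are scaled by it. `method = "bh"` is the same computation with
\(\pi_0 = 1\); families smaller than 100 tests always fall back to BH
because \(\pi_0\) estimation is unstable there.

## The synthetic-cohort generator

`generate_cohort()` draws cohorts with the structure the analyses assume.
Defaults describe the study conditions: 6100 genes, 165 lethal and 116
indolent samples. The generative model, per gene g and sample i on the log
scale:

\[ x_{gi} = \mu_g + \beta_g\,[\text{subtype}(i) \ni g] +
   e_g\,[\text{ERG}^+(i)] + t_g\,[\text{stroma}(i)] + \varepsilon_{gi} \]

* `mu_g` — baseline means drawn once, Normal(7, 1.5²) (typical log-intensity
  location/spread).
* `epsilon` — additive Gaussian noise, sd `noise_sd` (default 1); no
  gene–gene correlation beyond the block structure, by design.
* **Outcome signal.** `n_signal_genes` (default 100) split into K disjoint
  blocks, one per latent lethal subtype (`n_lethal_subtypes`, default 4);
  each lethal sample is assigned one subtype uniformly and only its block is
  shifted, so the class-level signal dilutes as 1/K. Effects have constant
  magnitude `effect_size_delta` (default 2) with **alternating signs**
  within a block: up- and down-regulated genes. The signs matter — a
  same-sign constant shift is invisible to correlation distances (Pearson is
  location-invariant per sample), which would blind the silhouette analysis
  to even perfectly separated classes. The default K = 4 emulates the
  heterogeneous-lethal-class regime these analyses were built to expose;
  K = 1 gives a molecularly homogeneous lethal class.
* **ERG subgroup.** The two class-conditional ERG+ probabilities are solved
  analytically so the lethality odds ratio equals `erg_target_odds_ratio`
  (default 7.2) at the marginal `erg_fraction` (default 0.16); infeasible
  combinations are rejected with the feasible range. Counts are allocated by
  stochastic rounding of the expected counts rather than per-sample
  Bernoulli draws: with only ~5 expected ERG+ indolent samples, the
  empirical odds ratio of Bernoulli draws is upward-biased by ~35% (Jensen),
  whereas count allocation concentrates it at the target. ERG+ samples carry
  an 87-gene signature whose per-gene effects are drawn once from
  N(δ_erg, δ_erg) — a coherent profile with gene-to-gene variation, again so
  that correlation distances can see it.
* **Stroma contamination.** A fraction of samples (default 17/281) carries a
  47-gene stroma profile, per-gene effects N(δ_str, δ_str) with δ_str = 2 —
  the same patterned-profile reasoning.
* **Clinical covariates.** Gleason bands are drawn conditional on outcome
  from a 3×2 table whose default targets the cohort-typical association
  strength (expected Cramér's V ≈ 0.45–0.47); age is Normal(74, 6²)
  truncated to [50, 95] (a placeholder — no distribution is canonical);
  lethal death times are lognormal with median 5 years, indolent follow-up
  uniform on 10–25 years, so only the ordering against the outcome
  definitions matters.

The generator is bit-reproducible given `seed`. Ground truth (gene blocks,
subtype labels, stroma flags, solved ERG probabilities) is returned
alongside the cohort and serialised as TSV sidecars by
`pipeline_simulate()`.

**What the generator does not emulate:** probe-level assay chemistry,
spatial tumour geometry, realistic gene–gene correlation (only block
structure), batch effects, and heavy-tailed noise. Tests passing on
synthetic cohorts therefore demonstrate the *statistical machinery* —
calibration, anti-leakage, parameter recovery, directional heterogeneity
effects — not performance on any real cohort.

## Extreme-case definitions

`apply_extreme_definition()` re-derives outcome labels from follow-up and
cause of death: lethal means cancer death (optionally within
`lethal_within_years`); indolent means no cancer death and follow-up of at
least `indolent_beyond_years` (default 10); everything else — death from
other causes, short follow-up, late cancer death under a stringent bound —
is excluded. Tightening the bounds purifies the classes at the cost of
cohort size.

## Numerical and design choices

* The per-gene test is the classic pooled-variance two-sample t-test
  (Welch selectable) — the era-typical microarray default.
* Fisher's exact test is computed exactly for 2×2 tables (hypergeometric
  tail with the customary 1e-7 relative tolerance for floating-point ties);
  larger tables use a seeded Monte-Carlo null with fixed margins, reported
  with its standard error — tractable and error-quantified, unlike
  network-algorithm enumeration.
* The odds-ratio interval is Woolf's log interval; zero cells get a 0.5
  continuity correction with a warning, zero margins are an error.
* Cramér's V uses the Pearson chi-squared statistic without continuity
  correction; zero-margin rows/columns are dropped with a warning.
* Missing values: operations that cannot tolerate missingness (t-tests,
  distances) drop genes with any missing value and report the count.
* Expression values are consumed as-is: assumed already log-scale and
  normalised; no normalisation, batch correction or probe collapsing is
  performed.
* kNN distance ties break to the smaller training index after a stable
  sort; stepwise selection ties break to the smaller gene set; model
  selection ties break to fewer genes, then the documented family order
  (dlda, logistic, knn, ntp, plugin).
* All randomness flows from one master seed through named substreams
  (split / folds / bootstrap / selection), echoed into every run manifest.

## Problem sizes used by the test suite

The packaged tests exercise the full protocol at the study scale where the
property under test demands it (6100 × 281 cohorts for null calibration
over 20 repetitions × 10 folds spread across 4 label permutations, effect
gradients, heterogeneity direction over 20 seeds, stroma flagging over 20
seeds) and at reduced scale (hundreds of genes, dozens of samples)
elsewhere; the reduced sizes are chosen so each property remains
well-powered, and the suites complete in well under an hour on one CPU.

## Known limitations

* The GEO importer's default characteristic-key mapping is a guess suitable
  for prostate watchful-waiting deposits; real records should be checked
  and the mapping overridden as needed. ERG status availability varies by
  deposit.
* NTP is implemented as cosine-distance template matching without the
  original permutation-based confidence; only the ranking score is needed
  for AUC evaluation.
* No native SVM or neural network (plug-in contract only), no probability
  calibration, no multiclass support, no survival-time modelling, no
  conditional-MLE odds ratios or stratified analyses.
* Silhouette groups beyond two are supported (b(i) is the nearest other
  group), but the analyses here use two outcome classes.
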