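---
title: "Composite immune-escape prognostic signatures: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite immune-escape prognostic signatures: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iegpi)
```

This vignette is the package's own account of the statistics it
implements: the models and their assumptions, the tunable parameters with
their defaults and units, what the synthetic-data generator does and does
not emulate, the numerical choices, and the known limitations.

## The two-stage signature model

The package targets the common clinical-transcriptomics design in which a
fixed panel of candidate genes (here: genes implicated in tumor immune
escape) is screened for prognostic value across several independent
cohorts, and the survivors are combined into one composite per-patient
score.

**Stage 1 — screening and pooling.** Within each cohort, each gene is
dichotomized at its own cohort median; the group with expression strictly
above the median is "high" and ties sit with the low group (a
deterministic, documented convention — medians computed on continuous
expression rarely tie in practice). A univariate Cox proportional-hazards
model on this indicator gives a per-cohort log hazard ratio with its
standard error. Per-cohort estimates are then pooled by inverse-variance
meta-analysis *on the log-HR scale*: pooling raw HRs is not standard
because the sampling distribution is asymptotically normal on the log
scale only. The fixed-effects estimator is `sum(w*b)/sum(w)` with
`w = 1/se^2`; the random-effects variant adds the DerSimonian–Laird
`tau^2` to every cohort variance. Both are available (`model =` in
`poolEffects()`/`runPipeline()`), fixed effects being the default: a
small, fixed set of cohorts analyzed with a common protocol is the setting
fixed-effects pooling describes, and the random-effects estimator
collapses to it whenever the moment estimate of `tau^2` is zero. Genes
absent from a cohort's platform are pooled over the remaining cohorts,
with the count recorded. Selection applies two thresholds to the pooled
results — raw `P < 0.001` and Benjamini–Hochberg `FDR < 0.001` by default
— and reports how many selected genes are poor-prognosis (HR > 1) versus
protective (HR < 1).

**Stage 2 — the composite score.** Each selected gene receives the weight

$$w_i = \frac{\mathrm{HR}_i - 1}{\mathrm{SE}_i},$$

a Wald-type ratio in which the numerator is the pooled hazard ratio's
excess over the null and the denominator its uncertainty. Because
`HR - 1` lives on the HR scale, the standard error is transported from
the log scale by the delta method, `SE_HR = HR * SE_log` (the log-scale
alternative sits behind `se_scale = "log"`). The weight is zero exactly
at HR = 1 and its sign always matches the prognosis direction. A sample's
score is `sum_i w_i * z_i`, where `z_i` is the gene's expression z-scored
*within its cohort*. Per-cohort standardization (rather than z-scoring a
merged cross-platform matrix) absorbs per-gene affine scale differences
between platforms, which is also why the score is invariant to per-gene
affine transforms of raw expression. The same scoring operation applies
unchanged to any genes-by-columns matrix — a bulk cohort, a merged
pan-cancer matrix, or a single-cell matrix — because nothing in it is
cohort-specific once the weights are frozen.

**Stratification.** The default cutoff is the maximally selected log-rank
statistic: every observed score value leaving both groups with at least
`min_group_fraction = 0.1` of the samples is a candidate, and the
candidate maximizing the two-group log-rank chi-square wins. The
alternative `youden_at_horizon` maximizes IPCW-weighted
sensitivity + specificity − 1 for the binary outcome "event by the
horizon" (default 36 months), for users who prefer an ROC-derived rule.
Because the maximally selected statistic is optimized in-sample, its
p-value is anticonservative for the *training* cohorts; the supported
external-validation path — scoring a held-out cohort with frozen weights
and applying the frozen cutoff — is the honest estimate of the split's
value, and `runPipeline()` enforces that no validation survival
information reaches screening, weighting or cutoff selection.

## Survival primitives and numerical choices

The survival layer is self-contained: the product-limit estimator, the
two-group log-rank test with hypergeometric variance, Cox partial
likelihood maximization and an IPCW cumulative/dynamic time-dependent
AUC.

- **Ties**: Breslow's approximation, not Efron's. At the tie rates the
  simulator produces (continuous times), the two are numerically
  indistinguishable, and Breslow keeps the hand-oracle in the test suite
  exact. The test suite cross-checks coefficients and standard errors
  against `survival::coxph(ties = "breslow")`.
- **Convergence**: Newton–Raphson stops at `max |score| < 1e-8` or a
  relative log-likelihood change below 1e-10, capped at 50 iterations;
  coefficients are clamped at |beta| = 20. Monotone-likelihood
  (separation) fits are *flagged*, not repaired: the screening stage
  records them as missing with a reason instead of propagating a
  boundary estimate.
- **Wald inference** is used throughout because the signature weights need
  standard errors anyway; the classical identity between the Cox score
  test and the log-rank chi-square (exact for untied data) is part of the
  acceptance suite.
- **Time-dependent AUC**: cases are subjects with an observed event at or
  before the horizon, controls those still under observation past it;
  pairs are weighted by inverse probabilities of censoring from the
  Kaplan–Meier estimate of the censoring distribution (cases at the left
  limit of their event time). With no censoring before the horizon this
  reduces to the plain Mann–Whitney AUC, which is how the implementation
  is tested.
- **ssGSEA**: for each sample, genes are ranked by decreasing expression
  with average ranks for ties; the enrichment score is the sum over the
  ranked list of the difference between the rank-weighted in-set ECDF
  (weights `rank^alpha`, `alpha = 0.25` as in the original single-sample
  formulation — the exponent is configurable) and the unweighted
  out-of-set ECDF. The score depends on ranks only, hence is invariant
  under strictly monotone transforms of a sample's profile. Per-set
  unity normalization rescales each row of the enrichment matrix to
  [0, 1]; constant rows map to zero with a warning. A set equal to the
  whole measured universe has no out-of-set ECDF and is rejected.
- **TMB**: nonsynonymous records (a documented nine-class whitelist of
  MAF `Variant_Classification` strings, matched case-insensitively)
  divided by a 38 Mb exome window; the window is configurable for other
  capture designs. Every record counts for TMB, but a gene counts at most
  once per sample in the mutation landscape and the per-gene Fisher
  tests — mirroring the usual burden-versus-oncoplot conventions. The
  Fisher p-value is the standard two-sided point-mass summation; the
  reported odds ratio is the sample OR with Haldane's 0.5 correction when
  a cell is zero (the conditional-MLE OR that `fisher.test` prints is a
  different estimand).

## What the simulator emulates — and what it does not

`simulateCohorts()` generates the design the analysis assumes: K
independent cohorts (default seven, with sample sizes 146, 267, 288, 125,
63, 66 and 182 — a realistic multi-study panel totalling 1137 patients),
a 182-gene panel of which 27 carry true effects, expression standard
normal on the analysis scale (the analysis z-scores anyway), survival
exponential with hazard `baseline * exp(sum_g beta_g * 1[expr_g >
median_g])`, baseline 0.03/month (median survival around two years,
typical of pancreatic adenocarcinoma series), effect magnitudes |log HR|
uniform in [0.4, 0.8] with configurable sign structure, and independent
exponential censoring whose rate is solved numerically (`uniroot` on the
expected censored fraction) to hit a 30% target. One master seed expands
into fixed per-component child seeds (a seeded `sample.int` stream), so
generating one component never perturbs another and every generator is
bit-reproducible. Companion generators produce gene sets (uniform draws
without replacement), mutation tables (Poisson record counts over a fixed
nonsynonymous/silent class mix, with optional per-group gene enrichment)
and immunotherapy-response cohorts calibrated to a target AUROC through
the binormal location shift `sqrt(2) * qnorm(auc)`.
`suppressImmuneSignature()` deterministically couples named (null) genes'
expression to the generated risk level, creating the
high-score/low-immune-infiltration pattern as a property of the design.

The simulator deliberately does **not** emulate RNA-seq count noise,
platform/batch effects, gene–gene correlation, probe-mapping loss, or
informative censoring. Passing tests therefore demonstrate that the
*statistical machinery* is correct and calibrated under the stated model
— not that the biological signature generalizes to real cohorts, where
cross-platform artifacts and confounding are the dominant risks.

## Marginal attenuation: a deliberate caveat

The generator's design intends the screening estimand to equal the
generating `beta` — which holds exactly when a single gene drives the
hazard, and is verified that way (a lone `beta = log 2` gene at n = 2000
is recovered within sampling error). When many genes act on the hazard
simultaneously, however, the *marginal* median-split Cox coefficient of
each gene is attenuated relative to its conditional `beta`: omitting the
other (independent) prognostic genes acts as frailty, and Cox hazard
ratios are not collapsible. With 27 genes at |log HR| in [0.4, 0.8] the
linear predictor carries a variance of about 1.8, and the marginal
estimates shrink to roughly 60% of the conditional values. This is a
property of proportional-hazards marginalization, not an estimation bug —
`survival::coxph` returns the same attenuated values — and it equally
affects any real study that screens genes one at a time: reported pooled
HRs from marginal screens understate conditional effects whenever several
true effects coexist. The package documents this rather than redefining
the generator's ground truth, and the parameter-recovery stress test in
the acceptance suite states its expectation against the conditional
`beta`, so its failure under joint effects is visible instead of painted
over.

## Problem sizes used by the test and acceptance suites

Calibration and property checks run on simulated designs sized to give
stable Monte-Carlo estimates while staying desk-scale: the null-FDR
calibration uses 200 replicates of 200 genes over three 300-sample
cohorts; parameter recovery uses 100 replicates of three 500-sample
cohorts; the end-to-end direction property uses 100 replicates of three
300-sample cohorts with a 40-gene panel; oracle equivalences use 20–50
random small instances each. These sizes are the package's choices for a
reproducible default run; all of them are ordinary function arguments and
scale up freely.

## Known limitations

- Cross-cohort integration happens at the *score* level (per-cohort
  z-scoring, pooled scores for the common cutoff); no expression-level
  merging or batch correction is attempted, so absolute score values are
  only comparable across cohorts up to the per-cohort standardization.
- The maximally selected cutoff's training-set log-rank p-values are
  anticonservative by construction; use the validation path for honest
  error rates.
- Breslow ties and Wald p-values are adequate for continuous expression
  and moderate event counts but would need revisiting for heavily tied
  discrete time scales or very sparse events.
- The ssGSEA immune score is a rank-based proxy for infiltration; it is
  not a deconvolution, and the 28-cell-type panels and immune signatures
  are user-supplied inputs, not shipped constants.
- Screening is marginal per gene; conditional effect sizes are attenuated
  whenever multiple true effects coexist (see above), which also bounds
  how literally the `(HR − 1)/SE` weights should be read as effect
  estimates.
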