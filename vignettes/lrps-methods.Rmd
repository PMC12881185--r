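---
title: "Constructing and validating a ligand-receptor pair signature for ICB response"
author: "lrpsig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing and validating a ligand-receptor pair signature for ICB response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lrpsig)
```

## The problem

Only a minority of patients with metastatic melanoma draw durable benefit
from immune checkpoint blockade (ICB). Because ICB remodels the tumor
microenvironment, biopsies taken *on treatment* carry information that
pre-treatment profiles miss, and much of that information is relational:
ligand-receptor (LR) signalling between tumor, immune and stromal cells.
`lrpsig` builds a ligand-receptor pair signature (LRPS) from on-treatment
bulk transcriptomes: each curated LR pair is reduced to a small gene set
(receptor complexes such as `ITGA2B/ITGB3` contribute every subunit), each
gene set is scored per sample, a sparse cost-sensitive classifier picks the
pairs that track response, and the signature is validated by
discrimination (ROC/AUC), response-rate stratification, and survival
analysis.

## Pair scoring: single-sample enrichment

Expression arrives as a genes-by-samples TPM matrix. Within each sample,
genes are ranked `1..N` with `N` the highest expression; ties are broken
by stable input order, which matters for two-gene sets and keeps every
result bit-reproducible. The enrichment score of a gene set $G$ walks the
ranked list from top to bottom and accumulates the gap between the
weighted in-set ECDF and the uniform out-of-set ECDF:

$$ES(G) = \sum_{i=1}^{N}\Big[\frac{\sum_{g \in G,\; pos(g) \le i} r_g^{w}}
{\sum_{g \in G} r_g^{w}} - \frac{|\{g \notin G : pos(g) \le i\}|}{N - |G|}\Big]$$

with rank-weighting exponent $w = 0.25$ by default. The sum has a closed
form used by `ssgseaScore()`; the test suite checks it against a naive
positional walk to $10^{-12}$. Because the statistic depends on ranks
only, any monotone per-sample transform (e.g. `log2(TPM+1)`) leaves scores
unchanged — convenient when cohorts arrive with inconsistent
preprocessing. Self-pairs (e.g. `LY9-LY9`) legitimately collapse to
single-gene sets and remain well-defined under this formula. Pairs with no
measured member genes are dropped with a warning; partially measured pairs
are scored on the measured subset so that platform differences between
cohorts do not silently shrink the signature. An optional global range
normalization (divide the whole matrix by its max minus min) is exposed
but off by default; the exponent and normalization are recorded in the
frozen signature so validation cohorts are scored identically.

## Cost-sensitive elastic-net selection

Response labels follow the RECIST-derived rule: responders (R) are
complete/partial response or progression-free survival beyond 180 days;
non-responders (NR) are progressive disease with PFS under 180 days;
everything else is "unknown" and excluded from fitting but still scored.

The classifier is an elastic-net penalized logistic regression of response
on pair scores (mixing $\alpha = 0.5$ by default, configurable; the L2
component matters here because informative pairs are correlated and pure
lasso tends to keep one representative of a correlated group). Cohorts of
on-treatment biopsies are small and imbalanced (about 21 R vs 33 NR in a
Riaz-like training cohort, 6 vs 29 in a Lee-like one), so the fit is made
cost-sensitive through a prior-probability offset on the log-odds scale,

$$o = \mathrm{logit}(\hat\pi) - \mathrm{logit}(\tau), \qquad
\hat\pi = \tfrac{n_R}{n_R + n_{NR}}, \quad \tau = 2/3,$$

added as a constant to the linear predictor of every training sample.

One subtlety deserves an honest paragraph. With an unpenalized intercept,
a constant offset that is included both during fitting *and* at prediction
is an exact no-op: the intercept absorbs it and fitted probabilities are
unchanged. The correction only does something if the offset is dropped
when predicting. `lrpsig` therefore trains with the offset and predicts
without it by default, which shifts predicted probabilities upward when
responders are the minority — the intended effect of weighting the
minority class without resampling. `sampleOdds(..., includeOffset = TRUE)`
exposes the inert alternative for comparison.

The regularization path is 100 log-spaced $\lambda$ values from the
data-derived $\lambda_{max}$ down to $0.001\,\lambda_{max}$. $\lambda$ is
chosen to maximize mean held-out AUC over 5 stratified folds
(stratification is essential: with 6 responders, unstratified folds can be
single-class). AUC is a rank statistic and saturates at exactly 1 over
long runs of the grid whenever the signal is strong, so "maximize AUC"
alone does not identify a model. Exact AUC ties are broken by the
parsimony-adjusted held-out deviance — mean cross-validated binomial
deviance plus an AIC-type penalty $2\,df/n$ — and any remaining ties go to
the largest $\lambda$. The deviance term distinguishes models the AUC
cannot (it rewards confident correct probabilities), while the complexity
penalty stops the selection from drifting into the noise region of the
path where spurious pairs enter. Coefficients are reported on the original
score scale (features are standardized internally by default).

## The LRPS and its decision rules

The signature score of a sample is the effect-size-weighted average of its
selected pair scores,

$$LRPS = \frac{\sum_j w_j s_j}{\sum_j |w_j|},$$

with the absolute-value denominator so that negative effect sizes cannot
flip or explode the score, and positive rescaling of all weights leaves it
unchanged. Each sample also gets the model's predicted probability
$1/(1+e^{-\eta})$ and per-sample odds $e^{\eta}$ (odds relative to even
odds; a centered variant $e^{\eta-\bar\eta}$ is exposed). Two thresholds
are frozen into the signature:

* the **Youden threshold** on the probability scale — candidates are the
  midpoints between consecutive sorted unique probabilities plus sentinels
  beyond the extremes, maximizing $J =$ sensitivity + specificity $- 1$,
  ties toward the smallest threshold (deterministic);
* the **high/low cutoff** — the arithmetic mean of the per-sample odds
  ratios, with "high" including equality. When a frozen signature is
  applied to a validation cohort the cutoff is recomputed from that
  cohort's own odds ratios by default (`orCutoff = "training"` reuses the
  training mean), because odds levels shift between cohorts while their
  ordering is what stratifies.

Validation never refits anything else: `runValidatePipeline()` scores the
new cohort with the signature's stored gene sets, exponent and
normalization, and errors (listing the genes) if a selected pair has no
measured member genes.

## Evaluation and survival validation

Discrimination is summarized by the ROC curve and AUC computed via the
Mann-Whitney identity with half-credit for ties, which makes the rank
formula and trapezoidal integration coincide exactly. Confusion metrics
(precision, recall, specificity, accuracy, F1) are reported both at the
Youden call and at the high/low grouping, since either can serve as the
classification rule; precision and F1 are `NA` when no positive call is
made. Group comparisons of scores use the one-tailed Wilcoxon rank-sum
test (R greater), exact by enumeration up to 12 tie-free observations and
normal-approximated with tie and continuity correction otherwise.
Association of the signature group with clinical covariates uses Pearson's
chi-square without continuity correction by default. No multiple-testing
correction is applied by default; p-values below 0.05 are reported as
significant and values in (0.05, 0.1] as trends.

Survival validation uses the Kaplan-Meier product-limit estimator, the
two-sided log-rank test between high and low groups, and Cox
proportional-hazards fits (Efron tie handling by default) for both the
group contrast and the continuous LRPS, with Wald 95% intervals. The
proportional-hazards assumption is checked with the global Schoenfeld
residual test on KM-transformed time (identity and rank transforms
available); PH is considered upheld when p > 0.05. Constant covariates are
reported with HR 1 and an infinite-variance warning instead of being
passed to the solver, and suspected monotone likelihood is flagged, not
clipped.

## What the synthetic cohorts emulate — and what they do not

Because the real cohorts live behind controlled-access repositories, every
stage is exercised on synthetic cohorts (`simulateCohort()`):

* log2 expression is Normal(`baselineMu` = 3, `noiseSd` = 1) per gene and
  sample, exponentiated to the TPM scale — log-normal expression noise at
  a spread typical of variable genes in bulk RNA-seq;
* a cohort of `nSamples` = 54 with responder fraction 21/54 by default,
  mirroring a Riaz-like training cohort; responder positions are drawn at
  random, i.e. labels are assigned by design rather than thresholded on
  the latent signal, so classification stays genuinely noisy;
* member genes of the designated informative pairs gain `delta` log2
  units in responders; the latent signal $z$ is the standardized mean
  log2 expression of those genes;
* PFS and OS are exponential with hazard
  $\lambda_0 e^{-\gamma z}$ ($\lambda_0$ = 0.005/day, i.e. a median around
  140 days at $z = 0$; OS at 60% of the PFS hazard), the simplest model
  satisfying proportional hazards exactly, with independent exponential
  censoring calibrated to a target censoring fraction (20% by default);
* the default catalog carries the seven melanoma signature pairs plus
  synthetic pairs over invented symbols, disjoint from background genes.

Deliberately absent: negative-binomial count noise and library-size
variation, batch effects, tumor purity, correlated co-expression modules,
and patient-level structure over multiple biopsies. Passing tests
therefore demonstrate that the machinery is correct and recovers planted
structure under realistic noise — not that the seven-pair melanoma
signature itself would re-derive from any particular real cohort.

Reproducibility contract: a single master seed drives per-component
sub-seeds (labels, expression, survival, censoring, covariates) at fixed
offsets, so identical `(config, seed)` give bit-identical cohorts, and
identical pipeline seeds give byte-identical model artifacts.

## Problem sizes and numerical choices in the test suite

The suite favors many small, deep checks: oracle equivalence of the
enrichment score on 100 random 50-gene instances; a from-scratch
coordinate-descent lasso-logistic oracle matched to $10^{-4}$ on a
5-feature, 40-sample toy; planted-pair recovery over 20 seeds of a
120-sample, 40-pair cohort with 5 informative pairs at `delta = 2`;
frozen-signature generalization over 10 train/validation seed pairs;
type-I-error calibration of the one-tailed Wilcoxon over 2,000 null
replicates and of the global Schoenfeld test over 1,000
proportional-hazards replicates; and Cox coefficient recovery at n = 500
over 50 replicates. These sizes keep the default run within a few minutes
while leaving the statistical bands (e.g. rejection rate in [0.03, 0.07]
at nominal 0.05) tight enough to catch calibration bugs.

## Known limitations

* The ssGSEA exponent, normalization and any pre-scoring transform are
  not uniquely determined by common practice; all are configuration, and
  frozen into the signature, but different choices give numerically
  different (rank-correlated) scores.
* The per-sample "odds ratio" is pinned to $e^{\eta}$, odds against even
  odds; other rescalings shift the high/low cutoff but not the grouping
  induced by any cohort-mean cutoff.
* Gene identifiers are matched case-sensitively with no alias resolution;
  cross-platform use should harmonize symbols upstream.
* With zero selected pairs (overwhelming regularization or no signal) the
  signature is degenerate: scoring errors out rather than imputing.
* Exponential survival with a log-linear hazard is the cleanest PH
  world; real follow-up with non-PH effects will show up in the
  Schoenfeld test rather than being modelled.
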