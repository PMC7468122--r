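---
title: "Multi-study co-expression and survival meta-analysis: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-study co-expression and survival meta-analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pancanGLI)
```

This vignette is the package's own account of its statistical machinery: the
models, the defaults and why they are what they are, what the synthetic-data
generator does and does not emulate, and the numerical choices that a
maintainer would otherwise have to reverse-engineer from the code.

## The analysis model

The pipeline treats a *study collection* — many independent expression
cohorts, each a genes × samples matrix with overall-survival annotations,
grouped into cancer types — as the unit of analysis. Nothing is ever pooled
at the sample level across datasets; every quantity is computed
*within* a dataset and then aggregated *across* datasets. This is the
defining design constraint: platforms, dynamic ranges and cohort case mixes
differ, so only unitless or standardized within-study statistics
(correlations, SD-unit coefficients, log hazard ratios per SD) are
comparable, and cross-study aggregation is done on those.

### Pre-treatment

Counts are upper-quartile normalized per sample: the scale factor is the
75th percentile (linear-interpolation quantile, the numerical-stack default;
nearest-rank selectable) of the sample's *nonzero* counts, which is robust
to zero inflation. Scaled values are multiplied by the mean factor so the
matrix keeps its overall magnitude. Then `log2(x + 1)`; the pseudocount of 1
is the conventional choice and only matters for very low counts. Array data
are assumed to arrive already on a log2 scale and pass through unchanged.
Probe-level rows are collapsed to gene symbols by the per-sample mean
(max-variance probe selectable); the collapse rule is a genuinely open
choice and the mean was picked as the least opinionated. Finally each gene
is z-scored across samples with the n−1 denominator. Zero-variance genes
have no defined z-score; they are dropped and reported in a mask rather than
set to 0, because a fabricated zero would silently enter downstream models.
The order is fixed: upper-quartile → log2 → aggregate → z-score.

### Co-expression

Within each dataset, each measured gene's Pearson correlation with GLI1 and
with GLI2 is computed (Pearson because the values are log-scale and
approximately continuous; Spearman is not offered as the correlation engine
default since z-scored log2 expression rarely has the heavy tails that would
demand it). Genes absent from a dataset are *missing*, never 0: absence of
measurement is not absence of correlation. Averaging across datasets is the
unweighted arithmetic mean of raw correlations over contributing datasets —
no Fisher-z transform and no sample-size weights by default, with both
available as options for sensitivity analysis. The pan-cancer average pools
all datasets in one stage by default; a two-stage variant (per-type means,
then across types) is provided because the two answer slightly different
questions when dataset counts are unbalanced across types. Gene ranking
uses mean-rank ties and reports percentile = 100·rank/n, so "top 20
percentiles" means percentile < 20. The focal 8×8 matrix is averaged per
cancer type and a pair is called positively correlated only when the
averaged r strictly exceeds 0.25 — an arbitrary but fixed threshold, and the
strictness at exactly 0.25 is tested.

### Metagenes

A signature's score in a sample is the mean of the signature genes'
zero-centred expression (no per-gene variance scaling; scaling is a flag).
Centring only means high-variance genes dominate the score — that is the
standard definition and is preserved; the score is z-scored later, alongside
genes, wherever it enters a model. Under a single-factor model in which k
genes each load on a driver with equal noise, the score's correlation with
the driver is √(k/(k+σ²)) — the closed form the tests check.

### Linear models

Per dataset, the z-scored metagene is regressed by OLS (with intercept,
which is 0 by construction for standardized data) on the eight z-scored
focal genes, and separately on three compound variables: the mean of member
z-scores for GLI = {GLI1, GLI2}, HH = {SHH, IHH, DHH}, TGFB =
{TGFB1, TGFB2, TGFB3}, each re-standardized so coefficients stay in SD
units. "Goodness of fit" is recorded as the Pearson correlation between
in-sample fitted and observed values (its square is exactly R²; the identity
is asserted to 1e−10). Collinear designs are resolved by minimum-norm least
squares via the SVD pseudo-inverse rather than by dropping predictors:
deterministic, order-independent, and it splits weight equally across
duplicated columns, which the tests pin down. Aggregation across datasets
of a cancer type is the unweighted mean of coefficients and of fit
correlations.

### Survival meta-analysis

Cohorts qualify with more than 50 patients (strict) and at least 10 death
events (inclusive). For each (cohort, variable), a univariate Cox
proportional-hazards model is fitted to the z-scored variable, so β is the
log hazard ratio per 1 SD. The partial likelihood is maximized by
Newton–Raphson with step-halving (the step is halved until the likelihood
does not decrease), starting at β = 0, converging when |score| < 1e−9 or
|Δβ| < 1e−10, capped at 50 iterations. Ties use the Efron correction by
default (the more accurate of the two standard corrections; Breslow is
selectable, and the two are verified to coincide to 1e−10 when there are no
ties). The standard error is the inverse square root of the observed
information at the optimum; p-values are two-sided Wald. Monotone
likelihoods — the covariate perfectly separates the event order, β drifting
to ±∞ — are detected (|β| > 15 or vanishing information) and flagged, and
flagged fits are excluded from pooling with a warning rather than
contributing a meaningless huge effect.

Per (cancer type, variable), log hazard ratios are pooled by
inverse-variance meta-analysis. The fixed-effect weights are 1/se²; the
random-effects model adds the DerSimonian–Laird moment estimate
τ² = max(0, (Q − (k−1))/(Σw − Σw²/Σw)) to every study variance. The
random-effects result is the headline (the conservative default when
between-study heterogeneity cannot be ruled out across platforms and
populations) and the fixed-effect result is always reported alongside.
Pooling happens on the log-HR scale; confidence intervals are exponentiated
for reporting. With k = 1 the pooled result is the study itself with
τ² = 0. No multiple-testing correction is applied by default — the
prognostic-score stage consumes raw p at fixed thresholds — and that is a
deliberate reporting convention, not an oversight.

### Prognostic profiles

The prognostic score of a (variable, cancer type) cell is log2(pooled HR)
when the meta-analytic p < 0.05 (strict), else 0. Zeros are *informative*
("no significant prognostic association"), so profile correlations across
cancer types are computed over the full score vectors including zeros
(Pearson by default, Spearman selectable). A variable whose profile has zero
variance has an undefined correlation, reported as missing rather than 0.
This profile correlation is the pipeline's headline statistic: concordant
GLI/TGFB profiles with a discordant, protective HH profile is the pattern
the whole analysis is designed to detect.

## The synthetic world

`sim_config()` states a generative world; its defaults are the conditions
the pipeline is tested under, chosen once:

- **Latent focal structure.** Per sample, the eight focal genes are drawn
  from a zero-mean multivariate normal with the configured correlation
  (validated symmetric/unit-diagonal; non-PSD matrices are repaired by
  eigenvalue clipping with a warning, and rejected if the repair moves any
  entry by more than 0.1).
- **Signatures.** Each signature gene is `loading × standardized driver +
  noise`, the driver being a weighted combination of focal genes; noise is
  scaled so every gene has unit latent variance. The single-factor design is
  intentional: it gives the metagene a known, analytic correlation with its
  driver, which turns linear-model recovery tests into closed-form checks.
- **Platforms.** A configurable fraction of datasets (default 0.25) is
  count-like: negative-binomial counts with log-mean linear in the latent
  (slope ln 2, so one latent SD is one log2 unit) and dispersion 0.2 —
  realistic overdispersion that genuinely exercises the upper-quartile +
  log2 path and attenuates a planted r = 0.6 to ≈ 0.42. The rest are
  array-like: per-gene offsets (uniform 4–10 log2 units), a dataset-wide
  scale (0.8–1.5), and measurement noise of SD 0.1 — small enough that a
  planted correlation of 0.6 is attenuated by under 0.01, which is what
  makes ±0.05 recovery bounds meaningful.
- **Background genes.** Default 200 independent standard-normal genes. This
  default was raised from an initial 50 during development: with only ~25
  genes in the panel, the per-sample upper-quartile factor is dominated by
  the focal genes themselves, and dividing by a factor correlated with the
  very genes under study visibly perturbs their correlations. Two hundred
  background genes emulate the stable normalization factor a real
  transcriptome provides. (A realism fix, not a tuning: no acceptance
  check uses count platforms.)
- **Survival.** Event hazard = baseline (default 0.1 per time unit) ×
  exp(Σ planted log-HR × standardized variable); exponential event times.
  Censoring combines an administrative horizon at the 70th percentile of
  the drawn event times with uniform dropout (default rate 0.35, raised
  from an initial 0.2 so that realized event fractions sit in the 30–60%
  band typical of clinical cohorts; measured ≈ 0.55–0.63).
- **Determinism.** Every dataset's seed is a stable polynomial hash of
  (master seed, cancer type, dataset index) reduced mod 2³¹−1, so outputs
  are identical regardless of generation order, and the ambient RNG state
  is saved and restored around generation.

What the generator does **not** emulate: tumor purity and stromal
admixture, batch effects needing correction, gene-length/GC biases,
non-proportional hazards, informative censoring, and any real biological
covariance beyond the planted low-rank structure. A green recovery test
therefore establishes that the pipeline's estimators are consistent and
calibrated *under the stated model* — not that the biological conclusions
drawn from real data are correct.

## Numerical and degenerate-input choices

- Quantile convention for the upper quartile: linear interpolation (type 7);
  nearest-rank (type 1) selectable.
- Samples with all-zero counts are an error naming the sample, not a silent
  NaN.
- Z-scoring requires ≥ 3 samples; correlation and profile-correlation
  stages likewise refuse fewer than 3 observations.
- The Cox solver insists on a non-decreasing likelihood at every accepted
  step; non-convergence with a non-trivial score is an error with
  diagnostics rather than a quietly wrong estimate.
- Ties in gene ranking take mean ranks, making percentiles
  permutation-equivariant.
- An averaged focal correlation exactly at the 0.25 threshold is *not*
  called positive (strict inequality).
- Minimum-norm least squares uses a relative singular-value cutoff of 1e−10.

## Open choices, resolved

Where the procedure was genuinely underdetermined, the package picks one
behaviour, documents it, and exposes the alternative: raw-r vs Fisher-z
averaging (raw default), unweighted vs sample-size-weighted dataset
averaging (unweighted), single- vs two-stage pan-cancer averages
(single-stage), mean vs max-variance probe collapse (mean), compound
variables as re-standardized mean z-scores (vs sum or first principal
component), Efron vs Breslow ties (Efron), random- vs fixed-effects headline
(random, both reported), Pearson vs Spearman profile correlations (Pearson),
coverage filtering by cancer types rather than datasets. Cox models are
fitted per dataset and pooled — never fitted on samples pooled across
datasets — because cross-study case-mix differences would otherwise
masquerade as covariate effects.

## Limitations

The Cox implementation is univariate by design; multivariable models,
time-varying effects and competing risks are out of scope. The
random-effects p-value uses a normal approximation, which is known to be
slightly liberal at very small k (the type-I calibration test runs at k = 4,
the collection's typical datasets-per-type ratio). Upper-quartile
normalization assumes enough expressed genes per sample for a stable 75th
percentile; panels of a few dozen genes violate that (see the background
genes note above). The generator's exponential baseline makes Kaplan–Meier
medians analytic but is not a claim about real survival curves.
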