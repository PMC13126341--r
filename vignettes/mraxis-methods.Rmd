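---
title: "Methods: estimators, diagnostics and design choices in mraxis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: estimators, diagnostics and design choices in mraxis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mraxis)
```

## The causal model

`mraxis` works entirely on marginal summary statistics: per-variant
effect estimates with standard errors from (at least) two
non-overlapping cohorts. The identifying assumptions are the usual
instrumental-variable ones — each selected variant is associated with
the exposure, independent of confounders of the exposure–outcome
relationship, and affects the outcome only through the exposure. The
third assumption (no horizontal pleiotropy) is the fragile one, and most
of the package exists to probe it: robust estimators that tolerate
partial violations, and diagnostics that detect directional violations.

For variant $i$, write $\hat\beta_{X_i}$ (SE $\sigma_{X_i}$) for its
exposure association and $\hat\beta_{Y_i}$ (SE $\sigma_{Y_i}$) for its
outcome association after harmonization to a common effect allele. The
per-variant causal estimate is the Wald ratio
$\hat\theta_i = \hat\beta_{Y_i}/\hat\beta_{X_i}$ with first-order SE
$\sigma_{Y_i}/|\hat\beta_{X_i}|$. We use only the first-order term: the
instrument-strength filter (F $\ge$ 10) bounds the relative error of
the expansion, and the package verifies the approximation against a
Monte-Carlo ratio distribution in its test suite.

## Instrument selection

`select_instruments()` applies, in order: genome-wide significance
(p < 5e-8), a minor-allele-frequency floor (0.01, with the effect-allele
frequency folded onto the minor-allele scale), greedy LD clumping
(r² < 0.1 within 10,000 kb against a user-supplied reference panel),
and the F $\ge$ 10 strength filter, F = (β/SE)². Each dropped variant
is logged under the first rule that removed it, so the selected set and
the exclusion log always partition the input.

Choices the underlying literature leaves open, fixed here:

* **F-statistic form.** The per-variant squared Wald statistic — the
  only form computable from the summary fields carried.
* **Filter order.** MAF before clumping: frequency is a property of the
  variant, LD structure of the region; removing low-frequency variants
  first prevents them from acting as clump indices. Clumping before the
  F filter is immaterial because p-ordering and F-ordering agree per
  variant.
* **Clump tie-breaks.** Equal p broken by ascending position, then
  variant id, so results are deterministic and order-invariant.
* **Variants absent from the panel** are retained as independent with a
  warning (strict mode drops them). A permissive default keeps analyses
  honest about what the panel covers without silently discarding
  signal.

## Harmonization

`harmonize()` aligns each shared variant to the exposure's effect
allele: identical alleles are kept, swapped alleles flip the outcome
beta (and complement its frequency), and strand complements are tried
before declaring a pair incompatible. Palindromic variants (A/T, C/G)
carry no strand information in their alleles, so allele frequencies
decide: missing frequency on either side excludes the variant;
frequencies within 0.5 ± 0.08 on either side are treated as
unresolvable and excluded; same-side frequencies keep the pair and
opposite sides flip it. The 0.08 band is the common community default;
it is a tunable argument because cohorts with very accurate frequency
estimates can justify a narrower band.

## Estimators

All estimators consume the harmonized pairs; `mr_fit()` bundles them
into one object with `print`/`summary`/`coef`/`confint`/`plot`/
`residuals`/`simulate` methods.

* **IVW** (primary): the zero-intercept weighted regression of outcome
  on exposure betas with weights $1/\sigma_{Y_i}^2$, equal to the
  inverse-variance-weighted mean of Wald ratios. The default SE uses a
  multiplicative random-effects residual scale *floored at 1*:
  overdispersion (heterogeneity) widens the SE, underdispersion never
  narrows it. A fixed-effect SE is available by flag; whether published
  analyses used fixed or random effects is usually unstated, and the
  random-effects form is the dominant convention.
* **MR-Egger**: the same regression with a free intercept, after
  orienting all exposure betas non-negative (the intercept is only
  interpretable on the oriented scale). The slope is the
  pleiotropy-adjusted estimate; slope inference uses the floored scale
  and a t distribution on k − 2 df.
* **Weighted median**: interpolated weighted median of the Wald ratios
  (inverse first-order-variance weights); consistent when valid
  instruments carry half the weight. SE by seeded parametric bootstrap.
* **Simple/weighted mode**: argmax of a Gaussian-kernel density of the
  ratios, bandwidth $0.9\,\min(\mathrm{SD},\ \mathrm{IQR}/1.349)\,
  k^{-1/5}$ times a user factor (default 1); consistent when the
  largest homogeneous cluster of instruments is valid. SEs share one
  seeded bootstrap.

### Numerical choices and degenerate inputs

* **Egger intercept test.** The slope SE convention (floored scale)
  deliberately never understates uncertainty, but applied to the
  intercept it makes the pleiotropy *test* conservative (about 3%
  rejection at nominal 5% in our calibration runs). Because the
  intercept is used as a hypothesis test with an interpreted level, it
  uses the exact weighted-least-squares t-test instead, which is
  exactly calibrated under the null. Degenerate guard: data lying
  numerically on an exact line (residual scale below 1e-8 of the
  response scale) report intercept p = 1 — a perfect fit is no evidence
  of pleiotropy, and the raw t-statistic is 0/0 there.
* **Bootstrap determinism.** Every bootstrap or simulation-based
  quantity takes an explicit seed and restores the caller's RNG state,
  so fits are bit-reproducible and never perturb user code.
* **All ratios equal.** Q is exactly 0 (p = 1); the mode estimators
  return the common value without density evaluation.
* **Single instrument.** IVW delegates to the Wald ratio (still
  reported as IVW); Q and the k ≥ 3 estimators report not-applicable
  rather than erroring.

## Sensitivity suite

`mr_sensitivity()` bundles Cochran's Q (first-order ratio weights,
fixed-effect centre, $\chi^2_{k-1}$), the Egger intercept test,
MR-PRESSO, the Steiger directionality test and leave-one-out.

**MR-PRESSO.** The observed statistic is the weighted residual sum of
squares of the leave-one-out IVW fits. Null replicates resample outcome
betas from their leave-one-out fitted means with the observed SEs,
*conditioning on the observed exposure betas*. (The original procedure
also perturbs exposure betas; the conditional form is used here because
it is the model under which the statistic is exactly calibrated for the
first-order weights used throughout the package.) The per-variant
outlier test compares each observed squared residual against its
simulated null with Bonferroni-style thresholding at 0.05/k; when
outliers are found, the IVW estimate is recomputed without them and a
distortion test compares the shift against the distribution of shifts
from removing equally many variants at random. Defaults: 5000
simulations, threshold 0.05/k.

**Steiger.** Per-variant $r^2 = t^2/(t^2 + n - 2)$ from the Wald
statistic, summed per trait; direction is TRUE when the instruments
explain more variance in the exposure than the outcome, with a z-test
on the difference of Fisher-transformed pooled correlations. For a
binary outcome the same form is applied to the log-odds Wald statistic
— a liability-scale approximation, adequate for the directionality
decision though not for interpreting the outcome $r^2$ itself.

**The gate.** A screened edge passes when (each criterion individually
switchable): heterogeneity is absorbed (random-effects IVW, or Q
p > α); Egger intercept p > α; PRESSO global p > α or the
outlier-corrected estimate concordant in sign; and Steiger direction
TRUE. Default α = 0.05, matching how such sensitivity tables are read.

## Mediation

`mr_mediation()` implements the two-step decomposition
$\beta_{12} = \beta_1\beta_2$ with the first-order delta SE
$\sqrt{\beta_1^2\sigma_2^2 + \beta_2^2\sigma_1^2}$ (the exact product
variance, adding $\sigma_1^2\sigma_2^2$, is available by flag), a
two-sided normal p-value, and proportion mediated
$\beta_{12}/\beta_{\mathrm{all}}$. The two legs are treated as
independent — they come from different instrument sets and cohorts in
the two-sample design. The proportion CI divides the $\beta_{12}$ CI by
a fixed $\beta_{\mathrm{all}}$ by default; a full-delta mode
propagating $\sigma_{\mathrm{all}}$ is provided, and neither is claimed
to be "the" published convention, which is typically not disclosed.
`screen_mediators()` keeps rows with p < 0.05 and proportion > 15%
(negative proportions — inconsistent mediation — can never pass). No
multiple-testing adjustment is applied by default, mirroring standard
practice in these screens; an FDR flag can be layered on by the user
via `p.adjust` on the returned table.

## The synthetic-data generators

Two generators with different jobs:

* `simulate_cohort()` — the three-trait chain genotype → exposure →
  mediator → outcome. Genotypes are Binomial(2, MAF) per variant
  (independent by default; a Gaussian-copula block mode emits a
  matching empirical LD panel for clump testing). Each trait is
  measured in its own independently simulated cohort, honouring the
  two-sample design; summary rows come from per-variant simple (or
  logistic) regression, exactly as public summary files are made. Only
  the exposure carries direct instrument effects; pleiotropy
  (fraction/mean/sd), outcome-beta outliers and palindromic rewrites
  are configurable corruptions. The implied total effect
  `direct + theta1*theta2` and every generating parameter are exposed
  as ground truth.
* `simulate_axis()` — four traits (upstream protein, downstream
  protein, metabolite, outcome) in which each molecular trait carries
  its own instruments, so every mediation leg is estimable. Defaults:
  causal effects 0.2 between molecular traits, 0.5 metabolite →
  outcome, direct (bypass) effects 0.1 and 0.15, instrument-effect SD
  0.25, n = 5000 per cohort — chosen so each trait has roughly 15
  genome-wide-significant instruments while a variant's *indirect*
  effect on a downstream trait (at most 0.2 × its own effect) would
  need an instrument effect about four SDs above scale to cross p <
  5e-8. That keeps each leg's selected instruments unbiased for that
  leg's total effect; true mediation proportions are 33% (upstream) and
  40% (downstream).

A third, `simulate_sumstats()`, draws harmonized betas directly on the
summary scale with outcome betas conditionally normal given exposure
betas. Under that conditional model Cochran's Q is exactly chi-square
and the Egger intercept t exactly t-distributed, so it is the generator
for the null-calibration studies; the individual-level generators serve
parameter recovery and end-to-end checks.

**What the generators do not emulate** — and hence what passing tests
do not show about real data: realistic effect-size and allele-frequency
spectra, genome-scale variant counts, population stratification, sample
overlap between cohorts, covariate structure, fine-scale LD, or
assay/batch artefacts. Recovery results certify the estimators and the
pipeline logic, not robustness to everything real summary files
contain.

## Study sizes and operating characteristics

The test suite and `scripts/acceptance.R` run: IVW recovery over 100
seeds (30 instruments, n = 5000/trait, true effect 0.15 — mean bias
well under 0.01, coverage ≈ 94%); axis recovery over 50 seeds;
1000-seed null calibrations of Q and the Egger intercept (both ≈ 5%);
50-seed PRESSO detection of a tenfold outlier (the outlier is injected
into a selected instrument of a strongly causal exposure — multiplying
a near-zero outcome beta by ten is a no-op, not an outlier); and a
10⁶-draw Monte-Carlo check of the delta-method SE (≈ 1% relative
error). Bootstrap sizes in the multi-fit recovery studies use 200
resamples; bootstrap SEs only feed the reported (non-gating) robust
estimators, so the reduced resolution does not affect recovery logic.

One interaction deserves emphasis. An axis spans three gated edges, and
the gate's component tests are *exactly calibrated* 5%-level tests — so
even a perfectly valid axis would trip at least one of six tests about
a quarter of the time. Recovery of an engineered axis at a ≥ 90% rate
is therefore impossible at per-test α = 0.05; it is a multiplicity
effect, not an estimator defect. The axis-recovery study accordingly
runs the gate at α = 0.01 per test (per-edge family control), while the
default for single-edge analyses stays 0.05. Users screening many
layers should make the same adjustment consciously.

## Known limitations

* First-order Wald SEs and weights throughout; very weak instruments
  (F near the 10 floor) inherit the usual weak-instrument attenuation.
* No correction for sample overlap between exposure and outcome
  cohorts; the two-sample assumption is the user's responsibility.
* Positions are matched by variant id only — no liftover, no proxy
  search.
* The binary-outcome Steiger comparison is a liability approximation.
* MR-PRESSO's conditional null understates exposure-side noise when
  instruments are weak; with the F filter in place the difference is
  negligible.
* No multivariable MR, no colocalization: an axis here is a chain of
  bivariate causal estimates plus mediation arithmetic, not a joint
  model.
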