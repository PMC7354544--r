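---
title: "Quantal bioassay analysis and mixture synergism with quantalmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantal bioassay analysis and mixture synergism with quantalmix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quantalmix)
```

## The model and its assumptions

A quantal bioassay records, for each tested concentration, how many larvae
out of those exposed were dead at a fixed scoring time. `quantalmix` models
the mortality of a group at concentration $c$ (ng/mL) with a logistic
tolerance distribution on natural-log dose:

$$\mathrm{logit}\, p(c) = b_0 + b_1 \ln c, \qquad
r \sim \mathrm{Binomial}(n,\, p(c)).$$

The assumptions are those of any grouped binomial dose-response model:
larvae respond independently within a well given the dose, tolerance is
log-logistically distributed across larvae, and mortality depends on the
inoculum only through its total concentration. Natural mortality is handled
separately: controls are stored as a zero-dose record (log-dose is undefined
at 0), and an optional Abbott correction rescales treated mortality when
control mortality is nonzero. In the bundled assays control mortality is
zero throughout, so the correction is off by default and is a no-op there
anyway.

Fitting is binomial maximum likelihood via iteratively reweighted least
squares (`stats::glm`), convergence tolerance $10^{-8}$, at most 100
iterations, started from the least-squares line through the empirical
logits (a 0.5-count continuity correction is applied to 0% and 100% groups
for the starting line only — the likelihood itself keeps the raw counts, and
extreme groups are never trimmed). Replicate wells at a concentration are
pooled before fitting; with dose as the only covariate this changes nothing
about the likelihood, which the test suite checks by splitting groups and
refitting.

## Lethal concentrations and fiducial limits

The LC$_p$ is the inverted tolerance curve,
$\mathrm{LC}_p = \exp\{(\mathrm{logit}\,p - b_0)/b_1\}$. Its 95% limits come
from Fieller's theorem applied to the ratio
$(\mathrm{logit}\,p - b_0)/b_1$ on the ln-dose scale, then exponentiated.
When the Fieller $g = z^2 \mathrm{var}(b_1)/b_1^2$ reaches 1 the interval is
unbounded and is reported as such with a warning rather than silently
truncated.

**Heterogeneity.** Grouped assays often vary more between doses than
binomial sampling allows (replicate wells differ in larval condition,
inoculum settling, feeding). The fit therefore carries a dispersion
estimate, Pearson $\chi^2$ divided by residual degrees of freedom. The
default policy (`"floor"`) inflates the covariance by the dispersion when it
exceeds 1 before computing limits — the classic quantal-assay practice.
Two alternatives are exposed: `"always"` (pure quasi-binomial scaling, also
downward when the fit is *under*-dispersed) and `"none"` (pure binomial).
The choice only affects interval estimates, never the point estimates.
Published coefficient tables in this field are not always consistent about
which policy they used, which is why reproduction of literature interval
estimates should be judged loosely even when point estimates match to three
digits.

## Parallelism and the mixture null model

Whether two treatments' regression lines share a slope is tested by fitting
the full grouped model with treatment-specific intercepts and slopes and
removing terms sequentially. The statistic is the quasi-likelihood F,

$$F = \frac{\Delta \mathrm{deviance} / \Delta \mathrm{df}}
          {\hat\phi_{\mathrm{full}}},$$

with $\hat\phi$ the full model's Pearson dispersion; the denominator degrees
of freedom are the full model's residual df (for two six-dose treatments:
$F$ on $(1, 8)$; for three: $(2, 12)$). The test is invariant to dataset
order and to rescaling all concentrations by a common factor.

Under **simple similar action**, mixture components behave as dilutions of
one another, so toxic units add and the expected mixture LC50 is the
proportion-weighted harmonic combination

$$\mathrm{LC50}(m) = \left[\frac{r_A}{\mathrm{LC50}(A)} +
\frac{r_B}{\mathrm{LC50}(B)}\right]^{-1},$$

with $r_A + r_B = 1$ the relative proportions by mass concentration. The
**synergism factor** is $\mathrm{SF} = \mathrm{LC50(expected)} /
\mathrm{LC50(observed)}$: above 1, potentiation; below 1, antagonism. The
null model assumes parallel component lines; when they are not parallel the
comparison is exact only at the 50% mortality point, so `synergy_table()`
annotates each mixture with a parallelism flag (`compare_slopes` at
$\alpha = 0.05$) and the SF should be read as an LC50-point statistic.

The harmonic form of the expected-LC50 rule is easy to misprint; it is
pinned down here by closed-form identities (equal components give back the
common LC50, $r_A = 1$ gives component A) and by the property that the
expected LC50 always lies between the component LC50s, both of which are
enforced in the test suite.

## Relative potency

Potency of a treatment against a reference is
$\mathrm{LC50(ref)}/\mathrm{LC50(trt)}$. Limits combine the delta-method
variances of the two $\ln$LC50s (independent fits) on the log-ratio scale
under the same heterogeneity policy. The reference's own potency is exactly
1 with degenerate limits.

## What the simulator emulates — and what it does not

`simulation_spec()` encodes a realistic larvicide assay: wells of 10-15
second-instar larvae (drawn uniformly per well), a 3.3-fold six-step
dilution series (default 2000 down to 8.2 ng/mL), three replicate wells per
concentration, binomial kills under the logit model, and controls that never
die. `mixture_simulation_spec()` builds a two-toxin experiment whose mixture
truth follows the simple-similar-action rule divided by a synergy multiplier
$s$ ($s = 1$ is additive), with the mixture slope defaulting to the mean of
the component slopes — the null model's parallel-lines idealisation — and a
dilution series centred on the mixture's true LC50.

Overdispersion is available as a beta-binomial with intra-well correlation
$\rho$: replicate standard deviations printed in real assay tables often
exceed binomial expectation, and $\rho > 0$ reproduces that inflation. The
default is $\rho = 0$ so that null calibration tests are exact.

What the generator does **not** emulate: time-to-death dynamics (only the
24 h endpoint), dose-measurement error, larval growth between instars,
plate/day blocking, and control mortality. Passing recovery tests therefore
demonstrate the statistical machinery is consistent and calibrated under the
stated sampling model, not that real assays are free of these further
sources of variation.

## Numerical choices and degenerate inputs

- Convergence: IRLS tolerance $10^{-8}$, 100 iterations; every fixture fit
  is also checked against an independent Nelder-Mead maximisation of the
  hand-written binomial log-likelihood (agreement to 4 decimals).
- Exactly two dose groups: the fit interpolates the empirical logits
  (saturated model, zero deviance); the dispersion is undefined there and
  treated as 1 for interval purposes.
- All-dead or all-alive series are rejected (the tolerance model is not
  identifiable); complete separation (a clean dose threshold) is flagged on
  the fit and its intervals are marked unreliable.
- Negative fitted slopes (mortality decreasing in dose) yield a warning but
  still return LC values, since screening pipelines need to see such fits
  rather than crash.
- Vanishing covariance collapses Fieller limits onto the point estimate;
  a negative Fieller discriminant can only arise from numerically degenerate
  covariances and is clamped to zero.

## Study design used in the bundled analyses

The simulation analyses shipped under `analysis/` and exercised by the test
suite use designs mirroring the bundled assays: single-treatment coverage
runs use the shallow-slope treatment (slope 0.59, LC50 279.37 ng/mL, its
printed dilution series) with seven replicate wells per dose (~85
larvae/dose) over 1000 runs; mixture calibration uses the two single-toxin
designs at three replicates with $s = 1$ over 200 runs; strong-synergy
recovery uses $s = 68.55$ with ten replicate wells (~120 larvae/dose) over
200 runs. At that design the dispersion of the recovered synergism factor is
appreciable — about 17% on the log scale, since three fitted LC50s enter the
statistic — so roughly 86% of runs land within 25% of the true fold-change;
halving that spread would take about four times the larvae. These problem
sizes keep the full suite to a few seconds on one CPU while leaving the
Monte-Carlo error of each check well below the width of its acceptance band.

## Known limitations

- Fiducial limits and potency limits are asymptotic; at very small group
  counts (a handful of wells) a parametric bootstrap on the fitted
  coefficients is the safer interval, and the test suite includes such a
  bootstrap as an oracle for the Fieller construction.
- The parallelism F-test uses grouped-data quasi-likelihood; replicate-level
  fits with a block structure could give materially different dispersion
  estimates, and published F statistics computed from unpublished
  replicate-level data may not be reproducible from pooled counts at all.
- Only binary mixtures are supported; the simple-similar-action rule
  generalises to more components, but the bundled assays and the report
  format are two-component.
- No independent-action (Bliss) null model and no isobologram analysis are
  provided.
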