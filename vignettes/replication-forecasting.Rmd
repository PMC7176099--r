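---
title: "Forecasting replication studies: model, evaluation machinery, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Forecasting replication studies: model, evaluation machinery, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(replicast)
```

## The problem

A replication project pairs each original study with one direct replication.
Before (or after) the replication is run, one can ask: given only the
original effect estimate and the two sample sizes, what distribution should
we assign to the replication effect estimate? `replicast` computes such
forecasts in closed form, evaluates them with the standard machinery for
probabilistic forecasts (proper scoring rules, calibration tests, PIT,
calibration slope, AUC), and provides the matching design tools
(replication probability, prediction intervals, sample-size planning).

All modelling happens on the Fisher-z scale: a correlation `r` estimated
from `n` observations is transformed to `theta_hat = atanh(r)`, which is
approximately normal with variance `1/(n - 3)`. Evaluation is done on this
scale too; the correlation scale is presentation-only (interval endpoints
are mapped through `tanh`, which is monotone and therefore preserves
coverage).

## The hierarchical model and its two priors

The generative model for a single pair is

* `theta ~ N(mu_theta, sigma_theta^2)` — the overall effect;
* `theta_o, theta_r ~ N(theta, tau^2)`, independently — study-specific
  effects, with `tau` the between-study heterogeneity;
* `theta_hat_k ~ N(theta_k, sigma_k^2)`, `sigma_k^2 = 1/(n_k - 3)` — the
  estimates.

Conditioning on the original estimate and integrating out the latent
effects gives a normal predictive distribution for the replication
estimate. Two priors on `theta` are supported:

* **Flat prior**: `theta_hat_r | theta_hat_o ~ N(theta_hat_o,
  sigma_o^2 + sigma_r^2 + 2 tau^2)`. At `tau = 0` this is the naive
  prediction-interval model used in the original replication-project
  analyses: centred at the original estimate, no shrinkage.
* **Sceptical prior**: a zero-mean normal with variance `g (sigma_o^2 +
  tau^2)` (a g-prior-type parametrization), with `g` fixed at its
  empirical-Bayes estimate `g_hat = max(t_o^2/(1 + d) - 1, 0)` (in relative
  terms). The predictive becomes `N(s theta_hat_o, s (sigma_o^2 + tau^2) +
  sigma_r^2 + tau^2)` with shrinkage factor `s = g_hat/(1 + g_hat) =
  max(1 - (1 + d)/t_o^2, 0)`. Shrinkage is *evidence-based*: weak originals
  (small `|t_o|`) are pulled strongly towards zero, and `s -> 1` as
  `t_o -> Inf`. For `d = 0` this is the classical optimal-shrinkage factor.

Crossing the two priors with `tau = 0` versus the default `tau = 0.08`
yields the four canonical methods `N`, `S`, `H`, `SH` (`rep_methods()`).

On the test-statistic scale the predictive depends only on the relative
quantities `t_o`, `c = sigma_o^2/sigma_r^2` and `d = tau^2/sigma_o^2`:
flat `N(sqrt(c) t_o, 1 + c(1 + 2d))`, sceptical
`N(s sqrt(c) t_o, s c (1 + d) + 1 + c d)`. The `sqrt(c)` factor in the mean
is forced by rescaling the z-scale predictive by `1/sigma_r` (and by the
`c = 1` case); the package enforces this consistency with a dedicated
invariant test.

## Parameters that matter

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `tau` | between-study heterogeneity SD (Fisher-z units) | 0.08 | see below |
| `alpha` | two-sided significance level defining "success" | 0.05 | convention of the replication projects |
| `level` | prediction-interval coverage | 0.95 | convention |

**Choice of `tau = 0.08`.** `tau` cannot be estimated from a single
original study, so a default is fixed by a plausibility device: under the
hierarchical model, 95% of study-specific underlying effects lie within
`theta ± 1.96 tau`; back-transformed at `theta = 0` the width of that range
is `delta(tau) = 2 tanh(1.96 tau)` (`delta_of_tau()`, inverted by
`tau_for_delta()`). `tau = 0.08` makes this width about 0.31 on the
correlation scale — about the size of a medium effect (`r = 0.3`) in
Cohen's classification, deliberately modest because direct replications are
matched closely to their originals. `tau_sensitivity()` traces the mean
scores over a `tau` grid so the sensitivity of any conclusion to this
default can be checked; the score-minimizing grid value also serves as a
crude heterogeneity estimate, since optimizing a mean proper score is a
valid estimation method.

**Significance definition.** A replication "succeeds" when it is two-sided
significant at `alpha` *and* has the same sign as the oriented original —
equivalently `t_r > z_{alpha/2}` after orientation. The forecast
probability uses the matching one-sided tail; the opposite-direction tail
`P(t_r < -z_{alpha/2})` is excluded by default (it is negligible for
realistic inputs) and can be included with `two_sided = TRUE`. With a
just-significant original, equal precision and no heterogeneity the flat
replication probability is exactly 0.5; the sceptical prior lowers it to
about 0.349.

**Orientation.** All analyses first flip pairs so `r_o >= 0`
(`orient_pairs()`, explicit and logged); "same direction" is undefined
otherwise. A pair with `r_o` exactly 0 is left alone; under the sceptical
prior it gets `s = 0` and a valid zero-mean forecast, and the design tools
report such targets as not attainable rather than erroring.

## Evaluation machinery

Continuous forecasts are scored with the logarithmic score (negative log
predictive density), the quadratic score (`-2 f(y) + integral(f^2)`), and
the CRPS in its closed form for normals; all negatively oriented, never
truncated. Binary probability-of-significance forecasts get the Brier
score and the normalized Brier score `(BS0 - BS)/BS0` against the
base-rate baseline.

Calibration is tested five ways:

1. **Spiegelhalter's z** for binary forecasts.
2. **Four score-based tests** for continuous forecasts, summarized by
   their plain harmonic mean `p_cal`: unconditional z-tests built on the
   exact null moments of the LS (`E = 0.5 log(2 pi v) + 0.5`,
   `Var = 0.5`) and of the CRPS (`E = sqrt(v/pi)`, `Var = kappa v`), plus
   two regression tests in which the individual score is regressed on its
   transformed predictive spread (LS on `log sqrt(v)`, CRPS on `sqrt(v)`
   with weights `1/v`) and the coefficients are tested jointly against
   their analytic calibrated values.
3. **PIT uniformity** via a one-sample Kolmogorov–Smirnov test (exact null
   distribution below n = 100).
4. **Calibration slope**: logistic regression of outcomes on
   logit-forecasts; complete separation is detected exactly (a threshold
   separating the classes) and flagged not estimable instead of fitted.
5. **Observed vs expected significant counts** via a two-cell chi-squared
   statistic on 1 df without continuity correction; the expected count is
   the sum of per-pair forecast probabilities and may be fractional.

Discrimination is measured by the midrank Mann–Whitney AUC with a DeLong
variance; its 95% Wald interval is built on the logit scale and
back-transformed, and a boundary AUC of exactly 0 or 1 is reported without
an interval. Paired score differences between methods are tested with a
paired t-test (or an optional seeded sign-flip permutation test).

## Numerical choices

* **`kappa` (CRPS variance constant).** The variance of `CRPS/sigma` under
  calibration in the standard-normal case has no simple closed form. It is
  computed once by adaptive quadrature (relative tolerance `1e-13`),
  validated against a 2×10^7-draw Monte Carlo run, and cached to 12 digits
  (`0.162751579442`).
* **Known-variance Wald form of the regression tests.** Under the
  calibration null the residual variance of both score regressions is
  known analytically (0.5 for the LS regression, `kappa` for the weighted
  CRPS regression), so the joint 2-df Wald statistic uses the known value
  rather than an estimate. In simulation at n = 73 this keeps the type-I
  error at the nominal 5% where the estimated-variance form is measurably
  anticonservative (about 7%). The joint (intercept, slope) test, rather
  than a slope-only test, is what gives these tests power against uniform
  overdispersion.
* **Root-finding and search.** `tau_for_delta()` inverts `delta_of_tau`
  by `uniroot` to `1e-10`. `required_replication_n()` first checks
  attainability against the analytic `c -> Inf` power limit (flat:
  `pnorm(t_o/sqrt(1 + 2d))`), then brackets by integer bisection and
  verifies local minimality; unattainable targets are reported as such
  (`attainable = FALSE`), not as errors.
* **Degenerate inputs.** Evaluations of very small projects return
  complete reports with `NA`/not-estimable entries where a measure needs
  more data (score-based tests below 3 pairs, slope/AUC with one outcome
  class); `n` is treated as a possibly non-integer effective sample size,
  hard-erroring only at `n <= 3`.

## The synthetic generator

`simulate_pairs()` draws projects from the hierarchical model itself. Its
defaults describe a modest social-science-like project, chosen once:
overall effects `N(0.2, 0.15^2)` on the z-scale (true correlations around
0.2), heterogeneity `tau = 0.08` (the package default), original sample
sizes uniform on 20..100 (covering variance ratios around 1/2..2 when
replications are of equal size, the default rule), and a two-sided 0.05
selection threshold when selection is switched on.

Publication-bias selection redraws the whole original triple
`(theta, theta_o, theta_hat_o)` until the original is significant — a
file-drawer model that selects *studies*, not estimates; replication
quantities are drawn afterwards, unconditionally. Selected originals are
therefore inflated relative to their underlying effects, which is exactly
the situation shrinkage is meant to repair; on such data the `SH` method
beats `N` on every mean score and the naive expected number of significant
replications exceeds the observed one, mirroring the qualitative pattern
seen in real projects.

`simulate_replications()` instead draws the replication estimate from a
*method's own predictive* given each original. Forecasts evaluated on such
draws are calibrated by construction, which makes this the reference
generator for nominal-level checks of the whole machinery: at 10^4 pairs
the 95% prediction-interval coverage is within ±0.01 of nominal, and over
1000 replicates of n = 73 all five calibration tests reject at 5% within
Monte Carlo error. Note that `simulate_pairs()` plus orientation does
*not* give exactly uniform PITs (the replication-minus-original difference
is correlated with the sign of the original estimate), so marginal
calibration checks on raw generator output are done without orientation.

What the generator does **not** emulate: non-normal likelihoods at small
n, p-hacking mechanisms beyond significance selection, many-to-one
replication designs, or dependence between pairs. Passing the
self-consistency suite therefore demonstrates internal correctness of the
forecasting-and-evaluation machinery, not that real replication data obey
the model.

## Problem sizes used in the checks

The test suite's simulation studies use: 10^5 replicates for the
Fisher-z variance check, 10^4 pairs for coverage, 1000 replicates of
n = 73 for the type-I study, and 100 selection-biased projects of n = 73
for the ordering checks. The heterogeneity-recovery experiment uses 500
pairs of *large* studies (n uniform on 150..500): an identifiability
analysis showed that with typical project-sized studies (n of 20..100)
the mean-CRPS criterion cannot pin `tau = 0.05` down to one step of a
0.01 grid at 500 pairs, so the recovery experiment — whose point is the
estimation logic, not project realism — uses a design under which the
parameter is identifiable.

## Limitations

* Normality of likelihood and prior is assumed throughout; at very small
  sample sizes the Fisher-z normal approximation weakens.
* `tau` is fixed, not estimated; a full-Bayes treatment with a prior on
  `tau^2` would propagate that uncertainty but lose the closed forms.
* Only the flat and empirical-Bayes zero-mean priors are implemented; a
  general informative normal prior is out of scope.
* Effect sizes enter as correlations; other effect measures would need
  their own variance-stabilizing transformation.
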