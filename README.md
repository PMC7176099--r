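# replicast

Probabilistic forecasting and evaluation of replication studies.

Large-scale replication projects pair each original study with one direct
replication. `replicast` answers two questions about such pairs:

1. **Forecasting** — given only the original effect estimate (a correlation
   `r_o` from `n_o` observations) and the replication sample size `n_r`,
   what normal distribution should we assign to the replication effect
   estimate?
2. **Evaluation** — once the replications are in, how good were those
   forecasts, in terms of calibration, discrimination, and sharpness?

## The model

On the Fisher-z scale (`θ̂ = atanh(r)`, `Var(θ̂) = 1/(n − 3)`) the package
assumes the hierarchical effect-size model

```
θ̂_k | θ_k ~ N(θ_k, σ_k²)        k ∈ {o, r}
θ_k | θ   ~ N(θ, τ²)             between-study heterogeneity τ
θ         ~ N(μ_θ, σ_θ²)         prior on the overall effect
```

and provides the two closed-form posterior predictive distributions of
`θ̂_r` given `θ̂_o`:

* **flat prior**: `N(θ̂_o, σ_o² + σ_r² + 2τ²)` — at `τ = 0` the classical
  "naive" prediction-interval model;
* **sceptical (empirical-Bayes g-type) prior**:
  `N(s·θ̂_o, s(σ_o² + τ²) + σ_r² + τ²)` with evidence-based shrinkage
  `s = max{1 − (1 + d)/t_o², 0}`, where `t_o = θ̂_o/σ_o` and
  `d = τ²/σ_o²`.

Crossing the priors with `τ = 0` versus the default `τ = 0.08` gives the
four canonical methods `N`, `S`, `H`, `SH`. Around the predictive
distributions sit proper scoring rules (LS, QS, CRPS, Brier), calibration
tests (Spiegelhalter z, four score-based tests with a harmonic-mean
summary, PIT + Kolmogorov–Smirnov, calibration slope), AUC, prediction
intervals, replication probabilities, sample-size planning, and a
synthetic project generator with optional publication-bias selection.

## Worked example

Simulate a significance-selected (publication-biased) project of 50 pairs
and evaluate all four methods:

```r
library(replicast)
library(dplyr)

pairs <- simulate_pairs(50, selection = TRUE, seed = 42)
ev <- evaluate_project(pairs, quiet = TRUE)
tidy(ev) |>
  select(method, qs, ls, crps, p_cal, coverage, observed, expected, chisq_p, bs)
#> # A tibble: 4 × 10
#>   method     qs    ls  crps     p_cal coverage observed expected   chisq_p    bs
#>   <chr>   <dbl> <dbl> <dbl>     <dbl>    <dbl>    <dbl>    <dbl>     <dbl> <dbl>
#> 1 N      -0.763 0.303 0.180 0.0000516     0.88       25     37.4 0.0000530 0.306
#> 2 S      -0.895 0.173 0.161 0.00224       0.9        25     33.5 0.0104    0.279
#> 3 H      -0.865 0.231 0.177 0.0294        0.92       25     36.3 0.000322  0.294
#> 4 SH     -1.00  0.101 0.156 0.225         0.94       25     31.7 0.0506    0.265
```

Reading the table: the mean quadratic (`qs`), logarithmic (`ls`) and
continuous ranked probability (`crps`) scores are all lowest for `SH` —
shrinkage plus heterogeneity gives the best forecasts of the replication
estimates on inflated originals. `p_cal` (harmonic mean of the four
score-based calibration tests) flags the naive method as clearly
miscalibrated while `SH` is not; the naive method expects 37.4 significant
replications where only 25 were observed (`chisq_p ≈ 5e-5`), whereas `SH`
expects 31.7; and the 95% prediction-interval coverage climbs from 88%
(`N`) to 94% (`SH`).

Design tools work pre-replication. For an original with `t_o = 2.8` and
`n_o = 53`, the replication sample size needed for 80% power:

```r
required_replication_n(2.8, n_o = 53, power = 0.8)                  # naive
#>     n_r power attainable
#>      71 0.802 TRUE
required_replication_n(2.8, n_o = 53, power = 0.8,
                       prior = "sceptical", tau = 0.08)             # SH
#>     n_r power attainable
#>     137 0.801 TRUE
```

Accounting for inflation and heterogeneity nearly doubles the required
sample size — targets that no sample size can reach (e.g. a fully shrunk
original) are reported as `attainable = FALSE` rather than an error.

A command-line interface wraps the same functions
(`inst/cli/replicast evaluate --input pairs.csv --out report.json`, plus
`simulate`, `power`, `ssize`, `sensitivity`); see `?cli_main`.

Per-result-type plots are available through `autoplot()` (PIT histograms,
prediction intervals, τ-sensitivity curves) and `plot_replication_probability()`,
`plot_shrinkage()`, `plot_delta_tau()`.

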