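# likertsim

Monte Carlo machinery for a question every survey analyst faces: **when is
it safe to treat an ordinal Likert response as a continuous variable** in
t-tests, linear regression, and correlation-based methods?

The package models the latent response intensity behind a k-point item as
a **rectified normal (RTN)** variable — a normal draw clipped to
`[-2, 2]`, leaving 95.4% of a centred distribution inside the range and
point masses on the limits that represent floor and ceiling effects — and
derives the Likert variable by cutting that range into k equal-width bins
mapped to the integers 1..k. Because the latent model is explicit, the
cost of discretization can be measured exactly and by simulation:

* **Effect-size attenuation.** Two-group effects are defined on the RTN
  scale by the heteroscedasticity-aware standardized mean difference
  d = (μ₁ − μ₂) / √((n₂σ₁² + n₁σ₂²)/(n₁ + n₂)); the calibrated latent
  shift then induces an attenuated d on each Likert transform, computed
  in closed form from exact clipped-normal and discretized moments.
* **Type-1 error and power** of the Welch t-test on single and merged
  (total-score) responses, with exchangeably correlated multivariate
  generation.
* **Required sample sizes** for a target power, by analytic inversion of
  the attenuated effect size (optionally simulation-refined).
* **Correlation-structure preservation** under discretization, scored by
  GFI and SRMR between the RTN and Likert sample correlation matrices.
* **Regression power** of the overall F-test with Likert responses and/or
  explanatory variables.

## Worked example

Attenuation is a property of the number of scale points, nearly constant
across effect sizes:

```r
library(likertsim)
run_effect_size_curve(es_grid = c(0.1, 0.3, 0.5))
#>    effect_size type  k  ratio
#> 1          0.1  RTN NA 1.0000
#> 2          0.1 2-pt  2 0.8019
#> 3          0.1 3-pt  3 0.9037
#> 4          0.1 4-pt  4 0.9436
#> 5          0.1 5-pt  5 0.9627
#> 6          0.1 6-pt  6 0.9733
#> 7          0.1 7-pt  7 0.9799
#> 8          0.3  RTN NA 1.0000
#> 9          0.3 2-pt  2 0.8007
#> ...
```

A two-point item keeps only ~80% of the latent effect size; from five
points the loss is under 5%. That translates directly into sample sizes
for 80% power at a small (0.1) latent effect:

```r
required_n_for_power("RTN", 0.1)
#> [1] 1570
required_n_for_power(2, 0.1)
#> [1] 2442
```

Power estimates come from the simulation drivers; each cell is a
rejection proportion ± binomial SE (in percent), every variable type
derived from the same latent draws within a replicate:

```r
cfg <- sim_config(effect_sizes = 0.2, sample_sizes = c(30, 100),
                  likert_points = c(2, 5), n_reps = 2000)
run_single_response_power(cfg)
#>   effect_size type  k n_per_group power    se ci_low ci_high n_reps n_degenerate
#> 1         0.2  RTN NA          30 10.55 0.687   9.20   11.90   2000            0
#> 2         0.2 2-pt  2          30  8.60 0.627   7.37    9.83   2000            0
#> 3         0.2 5-pt  5          30  9.95 0.669   8.64   11.26   2000            0
#> 4         0.2  RTN NA         100 31.55 1.039  29.51   33.59   2000            0
#> 5         0.2 2-pt  2         100 23.40 0.947  21.54   25.26   2000            0
#> 6         0.2 5-pt  5         100 29.00 1.015  27.01   30.99   2000            0
```

Read: at n = 30 per group and latent effect 0.2, the t-test on the latent
variable rejects in ~10.6% of replicates, the dichotomized version in
~8.6%; the five-point scale already tracks the latent variable closely.

See `vignettes/likert-as-continuous.Rmd` for the model, the generator's
design (coupled draws, per-cell seed streams), the GFI/SRMR definitions,
and every numerical choice.

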