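---
title: "Likert scales as continuous variables: model, design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Likert scales as continuous variables: model, design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(likertsim)
```

## The question

Survey instruments routinely record ordinal Likert responses — integer
levels 1 to k expressing intensity of agreement, satisfaction, or symptom
severity — and analysts routinely feed those integers into t-tests, linear
regressions, and correlation-based models built for continuous data.
`likertsim` quantifies what that shortcut costs. It posits an explicit
continuous latent response behind each item, derives the Likert variable
from it by a fixed measurement model, and compares the statistical
behaviour of the two representations: size and power of standard tests,
effect-size attenuation, sample-size inflation, and distortion of the
correlation matrix that factor-analysis-style methods consume.

## The latent model

The latent response intensity is modelled as a **rectified normal (RTN)**
variable: a normal draw clipped to a finite range, here `[-2, 2]` with unit
latent standard deviation, so that a centred latent distribution has 95.4%
of its mass strictly inside the range and point masses of about 2.3% on
each limit. The point masses are the model's representation of floor and
ceiling effects — respondents whose intensity exceeds what the scale can
express pile up on the extreme levels. This is deliberately different from
a truncated normal, which renormalizes the interior density and has no
boundary mass.

A k-point Likert variable is then the equal-interval discretization of the
RTN range: the interval `[-2, 2]` is cut into k bins of equal width and bin
j is recorded as integer level j. Both choices — the `±2` limits
(identified by the 95.4% coverage with unit latent scale) and the
equal-width bins — are fixed study conditions, not tuning knobs.

All moments used for calibration are exact. For the clipped normal,
`rtn_moments()` combines the censored-normal interior terms with the two
boundary masses; for the Likert transform, `lks_moments()` uses the exact
level probabilities (normal CDF differences with the boundary mass folded
into the extreme levels, `likert_probabilities()`).

## Effect sizes and calibration

Two-group comparisons use the heteroscedasticity-aware standardized mean
difference

$$d = \frac{\mu_1 - \mu_2}{\sqrt{(n_2\sigma_1^2 + n_1\sigma_2^2)/(n_1+n_2)}},$$

in which each group's variance is weighted by the opposite group's sample
size. Effect sizes are always *defined on the RTN scale*: group 1 sits at
latent mean 0 and group 2's latent mean is shifted by a value `delta`
calibrated (by bracketing bisection on the exact moments, residual below
1e-8; `calibrate_shift()`) so the RTN-scale d equals the nominal effect
size. The same shift then induces a smaller standardized difference on
each Likert transform; `effect_size_ratio()` computes that attenuation
exactly from moments. Two properties carry most of the study's message and
both are reproduced analytically here: the attenuation ratio depends
essentially only on the number of scale points (about 0.80 for two points,
above 0.95 from five points up), and it is constant across effect sizes in
`[0.1, 0.5]` to within 0.02.

The group-1 baseline at latent mean 0 is a design choice: only group 2 is
shifted. A symmetric `±delta/2` placement would make both groups' variances
change identically; with the one-sided shift the heteroscedastic effect
size is exercised as intended, and the calibration absorbs the (small)
variance change of the shifted group.

## The synthetic-data generator

All data are generated internally; there is no external dataset. The
generator (`mv_spec()`, `exchangeable_latent_sample()`,
`make_coupled_dataset()`, `two_group_dataset()`) draws exchangeably
correlated multivariate latent normals by the one-factor construction
`X_j = sqrt(rho) * C + sqrt(1 - rho) * U_j`, which realizes any common
pairwise correlation in `[0, 1]` exactly — including `rho = 1`, where all
columns coincide, without special-casing. The stated correlations are
interpreted as *latent* correlations, injected before clipping; clipping
and discretization then attenuate the observed correlations, which is
itself one of the phenomena under study. The observed (post-transform)
correlation is what the similarity experiment measures.

Within a replicate, every variable type (RTN and each point count) is
derived from the *same* latent draws ("coupling"). This mirrors the idea
of converting one underlying response into all candidate scale types, and
it sharpens comparisons between types by removing between-type sampling
noise. The regression driver extends the coupling across the
explanatory-variable counts as well: one replicate draws the maximal
variable set and every cell analyses a subset, so power differences across
cells are estimated with common random numbers. Independent draws per cell
remain available simply by running drivers with restricted grids and
different seeds.

What the generator deliberately does not emulate: non-normal latent
families (skewed, bimodal, heavy-tailed), unequal item difficulties or
loadings, non-exchangeable correlation structures, and negative
correlations. Conclusions drawn from passing tests therefore speak to
normal-derived latent responses with a common inter-item correlation; with
markedly non-normal latent distributions the detailed numbers would
change even though the qualitative ordering by scale points is expected to
persist.

## Experiments

Four drivers reproduce the study's designs, each cell estimated as a Monte
Carlo rejection proportion with binomial standard error
`sqrt(p(1-p)/n_reps)` (at the default 10,000 replicates the SE is at most
0.5 percentage points):

* `run_single_response_power()` — Welch t-test on a single response;
  effect sizes {0, 0.2, 0.5} × per-group n {30, 50, 100, 300, 500} × types
  RTN, 2–7 points.
* `run_merged_power()` — t-test on the sum of p correlated items (p in
  {2, 3, 5, 10}, latent rho in {0, 0.25, 0.5, 0.75, 1}), per-variable RTN
  effect size 0.2, n = 100 per group. For Likert cells the per-group n
  needed to match the same-cell RTN power is reported from the ratio of
  the merged scores' empirical effect sizes.
* `run_correlation_similarity()` — GFI and SRMR between the sample
  correlation matrix of the RTN columns and that of each Likert transform,
  n = 200, correlations below 1.
* `run_regression_power()` — overall F-test of OLS with q in
  {1, 2, 3, 5, 10} explanatory variables, all variables latently
  correlated at 0.2, n = 200, types up to five points. Required total
  sample sizes to match the RTN-explanatory reference are obtained by
  noncentral-F inversion on each cell's mean empirical
  `f² = R²/(1-R²)`, searched on an even-n grid.

The Welch test is used rather than Student's pooled test: the effect-size
definition explicitly accommodates heteroscedasticity, and with equal
group sizes and near-equal variances the two are numerically
indistinguishable anyway (`var_equal = TRUE` switches for sensitivity
runs). Required sample sizes for a *target* power (80%) come from the
closed-form normal-approximation inversion
`n = 2 (z_{1-α/2} + z_{power})² / d²` on the attenuated effect size
(`required_n_for_power()`), optionally refined by a local simulated
search in steps of 1.

### Fit measures

SRMR follows the printed formula exactly:
`sqrt(2 * sum_{i<=j} (a_ij - b_ij)^2 / (p (p+1)))`, the lower triangle
including the (vanishing) diagonal. GFI is `1 - F(A,B)/F(A,I)` where the
difference measure F had to be chosen: this package uses the squared
Frobenius distance over all entries, which makes `gfi(A, A) = 1` and
`gfi(A, I) = 0` exact and reproduces the qualitative behaviour of the
similarity experiment (notably the depressed GFI when the true correlation
is 0, because the reference matrix is then itself close to the identity
and the denominator is tiny). That same tiny denominator makes the
per-replicate GFI heavy-tailed at rho = 0, so GFI is validated by its
identities, its monotone improvement with scale points at positive
correlations, and the depressed rho = 0 column — not by digit-level
reproduction. SRMR, whose formula is fully specified, is reproduced
numerically.

## Numerical and degenerate-input choices

* Discretization bins are half-open on the left, `(e_{j-1}, e_j]`, with
  the lower limit absorbed into level 1. Interior edges carry zero
  probability, so this is purely a determinism convention.
* Likert levels are the integers 1..k; every downstream statistic is
  location/scale invariant, so the coding is cosmetic but fixed.
* Bisection for the calibrated shift runs on an auto-expanding bracket
  starting at `[0, 1]` with residual tolerance 1e-8; the map is strictly
  monotone so bracketing cannot fail.
* Replicates in which a test is degenerate — a merged score with zero
  variance in both groups, possible for coarse scales at small n — count
  as non-rejections and are tallied in the output (`n_degenerate`);
  replicates with an undefined correlation matrix are dropped and counted
  (`n_dropped`). Nothing is silently imputed.
* Seeding: each driver derives one RNG stream per cell (or per coupled
  cell block) by hashing the experiment name and cell label together with
  the master seed, so results are identical regardless of grid order or
  restriction, and reruns are byte-identical.

## Problem sizes

The full study grids at 10,000 replicates per cell reproduce every
reference cell within two printed standard errors and run in minutes. The
packaged test suite exercises the same drivers at 2,000 replicates for
cell-level reproduction (tolerance three binomial SEs at that count) and
at 400 replicates for structural patterns (monotonicity across scale
points), with exact-moment and quadrature checks at tolerance 1e-8 and
10^6–10^7-draw Monte Carlo oracle checks at three SEs. These sizes are the
package's chosen balance between resolution and a test suite that runs in
about a minute.

## Worked example

```{r}
cfg <- sim_config(effect_sizes = 0.2, sample_sizes = c(30, 100),
                  likert_points = c(2, 5), n_reps = 2000)
run_single_response_power(cfg)
```

```{r}
run_effect_size_curve(es_grid = c(0.1, 0.3, 0.5))
```

```{r}
required_n_for_power("RTN", 0.1)
required_n_for_power(2, 0.1)
```

## Limitations

The study conditions are a single latent family (clipped normal with fixed
limits), equal-interval discretization, exchangeable correlations, and
complete data. Within those conditions the package's conclusions are
precise; outside them — skewed latent responses, unequal thresholds,
missingness, structured correlation — it provides the machinery
(`rtn_spec()` accepts any mean/scale/limits; schemes accept any k) but no
claims. Fitting actual factor-analysis or structural-equation models is
out of scope: the similarity experiment compares correlation matrices
directly, which is what those models consume, without fitting them.
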