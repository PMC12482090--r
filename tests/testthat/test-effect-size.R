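test_that("standardized mean difference implements the cross-weighted formula", {
  mp <- function(m, v) moment_pair(m, v)
  expect_equal(standardized_mean_difference(mp(1, 1), mp(1, 2), 10, 20), 0)
  expect_equal(standardized_mean_difference(mp(1, 1), mp(0, 1), 50, 50), 1)
  # hand evaluation: (1-0)/sqrt((60*2 + 30*1)/90) = sqrt(90/150)
  expect_equal(
    standardized_mean_difference(mp(1, 2), mp(0, 1), 30, 60),
    sqrt(90 / 150)
  )
  expect_error(standardized_mean_difference(mp(1, 0), mp(0, 0), 5, 5),
               "degenerate")
})

test_that("calibrate_shift round-trips the target effect size", {
  expect_equal(calibrate_shift(0)$delta, 0)
  d <- calibrate_shift(0.2, n1 = 30, n2 = 30)
  realized <- standardized_mean_difference(
    rtn_moments(rtn_spec(d$delta)), rtn_moments(rtn_spec()), 30, 30
  )
  expect_lt(abs(realized - 0.2), 1e-6)
  # negative targets mirror positive ones
  expect_equal(calibrate_shift(-0.2)$delta, -calibrate_shift(0.2)$delta,
               tolerance = 1e-6)
})

test_that("calibrated shift agrees with a brute-force grid search", {
  # independent oracle: vectorized clipped-normal moments evaluated on a
  # fine delta grid, picking the grid point closest to the 0.5 target
  grid <- seq(0, 3, by = 1e-5)
  clip_mom <- function(mu) {
    a <- -2 - mu; b <- 2 - mu
    Fa <- pnorm(a); Fb <- pnorm(b); fa <- dnorm(a); fb <- dnorm(b)
    m <- -2 * Fa + 2 * (1 - Fb) + mu * (Fb - Fa) + fa - fb
    ex2 <- 4 * Fa + 4 * (1 - Fb) + mu^2 * (Fb - Fa) +
      2 * mu * (fa - fb) + (Fb - Fa + a * fa - b * fb)
    list(mean = m, var = ex2 - m^2)
  }
  base <- clip_mom(0)
  shifted <- clip_mom(grid)
  es_grid <- (shifted$mean - base$mean) / sqrt((shifted$var + base$var) / 2)
  d_oracle <- grid[which.min(abs(es_grid - 0.5))]
  expect_lt(abs(calibrate_shift(0.5)$delta - d_oracle), 1e-4)
})

test_that("attenuation ratio behaves across scale points and effect sizes", {
  ratios <- sapply(seq(0.1, 0.5, by = 0.1), function(es) {
    design <- calibrate_shift(es)
    sapply(2:7, function(k) effect_size_ratio(likert_scheme(k), design))
  })
  # monotone non-decreasing in k at every effect size
  expect_true(all(apply(ratios, 2, function(r) all(diff(r) >= 0))))
  # in (0, 1] everywhere on the grid
  expect_true(all(ratios > 0 & ratios <= 1))
  # nearly constant across the effect-size grid ("a single line")
  expect_true(all(apply(ratios, 1, function(r) diff(range(r)) < 0.02)))
  # refinement limit: a very fine scale loses almost nothing
  expect_lt(abs(effect_size_ratio(likert_scheme(1000), calibrate_shift(0.2)) - 1),
            0.01)
  expect_error(effect_size_ratio(likert_scheme(5), calibrate_shift(0)),
               "undefined")
})

test_that("moments are symmetric under mirroring the shift", {
  d <- calibrate_shift(0.3)$delta
  up <- rtn_moments(rtn_spec(d)); down <- rtn_moments(rtn_spec(-d))
  expect_equal(up$mean, -down$mean, tolerance = 1e-12)
  expect_equal(up$variance, down$variance, tolerance = 1e-12)
  for (k in c(2, 5)) {
    lu <- lks_moments(rtn_spec(d), likert_scheme(k))
    ld <- lks_moments(rtn_spec(-d), likert_scheme(k))
    expect_equal(lu$mean - (k + 1) / 2, (k + 1) / 2 - ld$mean,
                 tolerance = 1e-12)
    expect_equal(lu$variance, ld$variance, tolerance = 1e-12)
  }
})
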