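small_cfg <- function(...) {
  sim_config(n_reps = 400, seed = 7, ...)
}

test_that("drivers are reproducible from the configuration seed", {
  cfg <- small_cfg(effect_sizes = 0.2, sample_sizes = c(30, 50),
                   likert_points = c(2, 5))
  expect_identical(run_single_response_power(cfg),
                   run_single_response_power(cfg))
  cfg2 <- small_cfg(merge_counts = 2, rhos = c(0, 0.5), likert_points = c(2, 5))
  expect_identical(run_merged_power(cfg2), run_merged_power(cfg2))
  cfg3 <- small_cfg(merge_counts = 2, rhos = 0.5, likert_points = 5)
  expect_identical(run_correlation_similarity(cfg3),
                   run_correlation_similarity(cfg3))
  cfg4 <- small_cfg(n_explanatory = 1, likert_points = 2)
  expect_identical(run_regression_power(cfg4), run_regression_power(cfg4))
  # results do not depend on the order in which cells are requested
  cfg_rev <- small_cfg(effect_sizes = 0.2, sample_sizes = c(50, 30),
                       likert_points = c(2, 5))
  a <- run_single_response_power(cfg)
  b <- run_single_response_power(cfg_rev)
  key <- function(d) d[order(d$n_per_group, d$type), ]
  expect_equal(key(a)$power, key(b)$power)
})

test_that("power grows with the sample size at a fixed nonzero effect", {
  cfg <- sim_config(effect_sizes = 0.5, sample_sizes = c(30, 50, 100),
                    likert_points = c(2, 5), n_reps = 500, seed = 3)
  res <- run_single_response_power(cfg)
  for (tp in unique(res$type)) {
    rows <- res[res$type == tp, ]
    rows <- rows[order(rows$n_per_group), ]
    expect_true(all(diff(rows$power) > 0))
  }
})

test_that("required sample sizes follow the inverse-square law in the effect size", {
  es <- c(0.1, 0.2, 0.4)
  ns <- vapply(es, function(e) required_n_for_power("RTN", e), numeric(1))
  scaled <- ns * es^2
  expect_lt(diff(range(scaled)) / mean(scaled), 0.02)
  # Likert types always need at least as many samples as the latent variable
  expect_gte(required_n_for_power(2, 0.2), required_n_for_power("RTN", 0.2))
  expect_gte(required_n_for_power(5, 0.2), required_n_for_power("RTN", 0.2))
})

test_that("simulation refinement stays near the analytic inversion", {
  cfg <- sim_config(n_reps = 2000, seed = 5)
  n_analytic <- required_n_for_power("RTN", 0.5, cfg = cfg)
  n_refined <- required_n_for_power("RTN", 0.5, cfg = cfg, refine = TRUE)
  expect_lt(abs(n_refined - n_analytic) / n_analytic, 0.15)
})

test_that("merged power with perfectly correlated duplicates matches the single variable", {
  cfg <- sim_config(merge_counts = c(2, 5), rhos = 1, likert_points = 5,
                    n_reps = 1500, seed = 9)
  merged <- run_merged_power(cfg, es = 0.2, n_per_group = 100)
  single <- run_single_response_power(
    sim_config(effect_sizes = 0.2, sample_sizes = 100, likert_points = 5,
               n_reps = 1500, seed = 9)
  )
  for (p in c(2, 5)) {
    for (tp in c("RTN", "5-pt")) {
      pm <- merged$power[merged$merge_count == p & merged$type == tp]
      ps <- single$power[single$type == tp]
      se <- sqrt(merged$se[merged$merge_count == p & merged$type == tp]^2 +
                 single$se[single$type == tp]^2)
      expect_lt(abs(pm - ps), 3 * se)
    }
  }
})

test_that("regression power is symmetric in the roles for one explanatory variable", {
  set.seed(123)
  ds <- make_coupled_dataset(mv_spec(2, 0.2), list(likert_scheme(5)), 200)
  f_xy <- ols_overall_f_test(ds$rtn[, 1], ds$rtn[, 2])
  f_yx <- ols_overall_f_test(ds$rtn[, 2], ds$rtn[, 1])
  expect_equal(f_xy$p_value, f_yx$p_value, tolerance = 1e-12)
})

test_that("effect-size curves are exact for the latent type and attenuated otherwise", {
  curve <- run_effect_size_curve(es_grid = c(0.1, 0.3, 0.5))
  expect_true(all(curve$ratio[curve$type == "RTN"] == 1))
  two <- curve$ratio[curve$type == "2-pt"]
  expect_lt(diff(range(two)), 0.02)
  expect_true(all(curve$ratio[curve$k >= 5] >= 0.95, na.rm = TRUE))
  # simulated ratios track the analytic ones
  sim <- run_effect_size_curve(sim_config(n_reps = 800, seed = 13),
                               es_grid = 0.3, simulate = TRUE)
  expect_lt(max(abs(sim$ratio_sim - sim$ratio)), 0.05)
})
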