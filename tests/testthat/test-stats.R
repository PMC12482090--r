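test_that("welch_t_test matches the reference implementation", {
  x <- c(1.1, 2.3, 0.7, 1.9, 1.2)
  y <- c(2.4, 3.1, 2.9, 1.8, 2.2)
  got <- welch_t_test(x, y)
  ref <- t.test(x, y)
  expect_lt(abs(got$statistic - unname(ref$statistic)), 1e-10)
  expect_lt(abs(got$df - unname(ref$parameter)), 1e-10)
  expect_lt(abs(got$p_value - ref$p.value), 1e-10)
  # identical samples: no evidence at all
  same <- welch_t_test(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # affine invariance
  shifted <- welch_t_test(3 * x + 2, 3 * y + 2)
  expect_equal(shifted$statistic, got$statistic, tolerance = 1e-12)
  expect_error(welch_t_test(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("column-wise Welch p-values agree with t.test over random replicates", {
  set.seed(66)
  x1 <- matrix(rnorm(30 * 50), 30)
  x2 <- matrix(rnorm(40 * 50, 0.3), 40)
  p_fast <- likertsim:::welch_p_cols(x1, x2)$p
  p_ref <- vapply(1:50, function(j) t.test(x1[, j], x2[, j])$p.value,
                  numeric(1))
  expect_equal(p_fast, p_ref, tolerance = 1e-12)
  # degenerate columns count as non-rejections
  w <- likertsim:::welch_p_cols(matrix(1, 10, 2), matrix(2, 10, 2))
  expect_equal(w$p, c(1, 1))
  expect_equal(w$n_degenerate, 2)
})

test_that("welch test keeps its nominal size under the null", {
  for (n in c(30, 500)) {
    set.seed(1000 + n)
    x1 <- matrix(rnorm(n * 10000), n)
    x2 <- matrix(rnorm(n * 10000), n)
    rate <- mean(likertsim:::welch_p_cols(x1, x2)$p < 0.05)
    expect_gte(rate, 0.045)
    expect_lte(rate, 0.055)
  }
})

test_that("overall F-test matches lm and collapses duplicated columns", {
  set.seed(77)
  X <- matrix(rnorm(60), 20, 3)
  y <- X %*% c(0.5, 0, -0.3) + rnorm(20)
  got <- ols_overall_f_test(y, X)
  ref <- summary(lm(y ~ X))
  expect_lt(abs(got$statistic - ref$fstatistic[["value"]]), 1e-10)
  expect_lt(abs(got$p_value -
                pf(ref$fstatistic[[1]], ref$fstatistic[[2]],
                   ref$fstatistic[[3]], lower.tail = FALSE)), 1e-12)
  # q = 1: F is the squared slope t statistic
  g1 <- ols_overall_f_test(y, X[, 1])
  t1 <- summary(lm(y ~ X[, 1]))$coefficients[2, ]
  expect_equal(g1$statistic, unname(t1["t value"])^2, tolerance = 1e-10)
  expect_equal(g1$p_value, unname(t1["Pr(>|t|)"]), tolerance = 1e-12)
  # a duplicated column (latent correlation 1) collapses to the same test
  gd <- ols_overall_f_test(y, cbind(X[, 1], X[, 1]))
  expect_equal(gd$statistic, g1$statistic, tolerance = 1e-10)
  expect_error(ols_overall_f_test(y, matrix(1, 20, 2)), "degenerate")
})

test_that("gfi and srmr reproduce hand algebra and identities", {
  A <- matrix(c(1, 0.5, 0.5, 1), 2)
  B <- matrix(c(1, 0.4, 0.4, 1), 2)
  expect_equal(gfi(A, A), 1)
  expect_equal(gfi(A, diag(2)), 0)
  expect_equal(gfi(A, B), 1 - (2 * 0.01) / (2 * 0.25))
  expect_error(gfi(diag(2), B), "identity")

  expect_equal(srmr(A, A), 0)
  expect_equal(srmr(A, B), sqrt(2 * 0.01 / 6))
  expect_equal(srmr(A, B), srmr(B, A))
})

test_that("gfi and srmr are invariant to joint row/column permutation", {
  set.seed(88)
  x <- matrix(rnorm(500 * 4), 500, 4)
  y <- x + matrix(rnorm(500 * 4, sd = 0.5), 500)
  A <- cor(x); B <- cor(y)
  perm <- c(3, 1, 4, 2)
  expect_equal(gfi(A, B), gfi(A[perm, perm], B[perm, perm]), tolerance = 1e-12)
  expect_equal(srmr(A, B), srmr(A[perm, perm], B[perm, perm]),
               tolerance = 1e-12)
})

test_that("srmr of independent sample correlation matrices shrinks like 1/sqrt(n)", {
  set.seed(99)
  ns <- c(100, 400, 1600)
  means <- vapply(ns, function(n) {
    mean(replicate(150, {
      srmr(cor(matrix(rnorm(n * 3), n)), cor(matrix(rnorm(n * 3), n)))
    }))
  }, numeric(1))
  slope <- coef(lm(log(means) ~ log(ns)))[2]
  expect_lt(abs(slope + 0.5), 0.1)
})

test_that("proportion_estimate implements the binomial SE and clipped CI", {
  e <- proportion_estimate(5000, 10000)
  expect_equal(e$se, 0.005)
  e0 <- proportion_estimate(0, 400)
  expect_equal(e0$p_hat, 0)
  expect_equal(e0$se, 0)
  e2 <- proportion_estimate(494, 10000)
  expect_equal(e2$p_hat, 0.0494)
  se <- sqrt(0.0494 * (1 - 0.0494) / 10000)
  expect_equal(e2$ci_low, 0.0494 - 1.96 * se)
  expect_equal(e2$ci_high, 0.0494 + 1.96 * se)
})
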