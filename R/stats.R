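#' Welch two-sample t-test
#'
#' Unequal-variance t-test with Satterthwaite degrees of freedom, the
#' default comparison used by every power experiment (the effect-size
#' definition is itself heteroscedasticity-aware). Thin wrapper around
#' [stats::t.test()] returning only the statistic, df, and two-sided
#' p-value. Set `var_equal = TRUE` for Student's pooled test in sensitivity
#' runs.
#'
#' @param x,y Numeric vectors, each with at least 2 observations.
#' @param var_equal Use the pooled-variance (Student) test instead.
#' @return A list of class `test_result` with `statistic`, `df`, `p_value`.
#' @examples
#' welch_t_test(rnorm(30), rnorm(30, 0.5))
#' @export
welch_t_test <- function(x, y, var_equal = FALSE) {
  stopifnot(is.numeric(x), is.numeric(y))
  if (length(x) < 2 || length(y) < 2) {
    stop("each group needs at least 2 observations", call. = FALSE)
  }
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    stop("degenerate input: zero variance in both groups", call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = var_equal)
  structure(
    list(statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> statistic = %.4f, df = %.2f, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

# Column-wise Welch p-values for replicate matrices (one replicate per
# column). Degenerate columns (zero variance in both groups) get p = 1 so
# they count as non-rejections; their number is returned for the run log.
welch_p_cols <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1 * x1) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2 * x2) - n2 * m2^2) / (n2 - 1)
  v1 <- pmax(v1, 0); v2 <- pmax(v2, 0)
  se2 <- v1 / n1 + v2 / n2
  bad <- se2 <= 0
  se2[bad] <- 1
  tstat <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  df[bad] <- 1
  p <- 2 * stats::pt(-abs(tstat), df)
  p[bad] <- 1
  list(p = p, n_degenerate = sum(bad))
}

#' Overall F-test of a linear regression
#'
#' Fits ordinary least squares of `y` on `X` with an intercept always
#' included and returns the overall F-test of all slopes against the
#' intercept-only model. Duplicate or collinear columns (which arise when
#' latent correlation 1 duplicates variables) are collapsed by the QR rank
#' before testing.
#'
#' @param y Response vector.
#' @param X Design matrix (`n x q`), without intercept.
#' @return A `test_result` with the F statistic, numerator df, and p-value
#'   (the list carries `df` = numerator df and `df2` = denominator df).
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(200), 100, 2)
#' ols_overall_f_test(X %*% c(0.3, 0) + rnorm(100), X)
#' @export
ols_overall_f_test <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  stopifnot(nrow(X) == n)
  Z <- cbind(1, X)
  qz <- qr(Z)
  rank <- qz$rank
  q_eff <- rank - 1L
  if (q_eff < 1L) {
    stop("degenerate design: no non-constant explanatory variable remains",
         call. = FALSE)
  }
  if (n <= rank) stop("need n > number of fitted coefficients", call. = FALSE)
  res <- qr.resid(qz, y)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df2 <- n - rank
  fstat <- ((tss - rss) / q_eff) / (rss / df2)
  structure(
    list(statistic = fstat, df = q_eff, df2 = df2,
         p_value = stats::pf(fstat, q_eff, df2, lower.tail = FALSE)),
    class = "test_result"
  )
}

# fast overall-F p-value used inside simulation loops (full-rank designs)
ols_f_p <- function(y, X) {
  Z <- cbind(1, X)
  fit <- stats::lm.fit(Z, y)
  rank <- fit$rank
  q_eff <- rank - 1L
  if (q_eff < 1L) return(1)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  df2 <- length(y) - rank
  fstat <- ((tss - rss) / q_eff) / (rss / df2)
  stats::pf(fstat, q_eff, df2, lower.tail = FALSE)
}

check_corr_pair <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  p <- nrow(A)
  if (ncol(A) != p || !all(dim(B) == c(p, p))) {
    stop("A and B must be square matrices of the same dimension", call. = FALSE)
  }
  list(A = A, B = B, p = p)
}

#' Goodness-of-fit index between two correlation matrices
#'
#' `gfi = 1 - F(A, B) / F(A, I)` with `F` the squared Frobenius distance
#' (sum of squared elementwise differences over all entries): the relative
#' improvement in closeness of `B` to the reference `A` over the identity
#' matrix. Equals 1 iff `A == B`, 0 when `B` is the identity, and is
#' unbounded below. Undefined when `A` is itself the identity.
#'
#' @param A Reference correlation matrix.
#' @param B Comparison correlation matrix.
#' @return The index (a real number, at most 1).
#' @examples
#' A <- matrix(c(1, .5, .5, 1), 2); B <- matrix(c(1, .4, .4, 1), 2)
#' gfi(A, B) # 0.96
#' @export
gfi <- function(A, B) {
  m <- check_corr_pair(A, B)
  denom <- sum((m$A - diag(m$p))^2)
  if (denom == 0) {
    stop("undefined denominator: reference matrix equals the identity",
         call. = FALSE)
  }
  1 - sum((m$A - m$B)^2) / denom
}

#' Standardized root mean squared residual between correlation matrices
#'
#' \deqn{SRMR = \sqrt{2 \sum_{i=1}^{p}\sum_{j=1}^{i}
#'   \frac{(a_{ij}-b_{ij})^2}{p(p+1)}}}
#' summing the lower triangle including the diagonal (whose terms vanish for
#' correlation matrices). Zero iff the lower triangles agree; values under
#' 0.05 are conventionally regarded as excellent agreement.
#'
#' @inheritParams gfi
#' @return Nonnegative real.
#' @examples
#' A <- matrix(c(1, .5, .5, 1), 2); B <- matrix(c(1, .4, .4, 1), 2)
#' srmr(A, B) # sqrt(2 * 0.01 / 6)
#' @export
srmr <- function(A, B) {
  m <- check_corr_pair(A, B)
  lt <- lower.tri(m$A, diag = TRUE)
  sqrt(2 * sum((m$A - m$B)[lt]^2) / (m$p * (m$p + 1)))
}

#' Monte Carlo proportion with standard error and confidence interval
#'
#' Converts a rejection count into a proportion with the binomial standard
#' error `sqrt(p(1-p)/n)` and a normal-approximation 95\% interval clipped
#' to `[0, 1]`. At 10,000 replicates the standard error is at most 0.5
#' percentage points (attained at p = 0.5).
#'
#' @param rejections Number of rejections (0..n_reps).
#' @param n_reps Number of replicates.
#' @return An object of class `power_estimate` with `p_hat`, `n_reps`,
#'   `se`, `ci_low`, `ci_high`.
#' @examples
#' proportion_estimate(494, 10000)
#' @export
proportion_estimate <- function(rejections, n_reps) {
  stopifnot(n_reps >= 1, rejections >= 0, rejections <= n_reps)
  p_hat <- rejections / n_reps
  se <- sqrt(p_hat * (1 - p_hat) / n_reps)
  structure(
    list(p_hat = p_hat, n_reps = as.integer(n_reps), se = se,
         ci_low = max(p_hat - 1.96 * se, 0),
         ci_high = min(p_hat + 1.96 * se, 1)),
    class = "power_estimate"
  )
}

#' @export
print.power_estimate <- function(x, ...) {
  cat(sprintf("<power_estimate> %.2f%% +/- %.2f%% (95%% CI %.2f%% - %.2f%%; %d reps)\n",
              100 * x$p_hat, 100 * x$se, 100 * x$ci_low, 100 * x$ci_high,
              x$n_reps))
  invisible(x)
}
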