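# Numerical-quadrature oracle for the moments of a clipped normal:
# interior integral plus the two boundary point masses. Independent of the
# closed-form path in rtn_moments().
quad_rtn_moments <- function(mu, sigma = 1, lower = -2, upper = 2) {
  f <- function(x, pow) x^pow * dnorm(x, mu, sigma)
  p_lo <- pnorm(lower, mu, sigma)
  p_hi <- pnorm(upper, mu, sigma, lower.tail = FALSE)
  m <- integrate(f, lower, upper, pow = 1, rel.tol = 1e-12)$value +
    lower * p_lo + upper * p_hi
  ex2 <- integrate(f, lower, upper, pow = 2, rel.tol = 1e-12)$value +
    lower^2 * p_lo + upper^2 * p_hi
  c(mean = m, variance = ex2 - m^2)
}

# tolerance of +/- 3 binomial SEs around a proportion p0 (as a percent)
#  at the given replicate count
pct_tol3 <- function(p0_pct, n_reps) {
  p <- p0_pct / 100
  3 * sqrt(p * (1 - p) / n_reps) * 100
}
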