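#' Heteroscedasticity-aware standardized mean difference
#'
#' Two-group effect size
#' \deqn{d = \frac{\mu_1 - \mu_2}{\sqrt{(n_2\sigma_1^2 + n_1\sigma_2^2)/(n_1+n_2)}}}
#' an extension of Hedges' d in which each group's variance is weighted by
#' the opposite group's sample size, so unequal variances and unequal group
#' sizes are both accounted for. With equal group sizes it reduces to the
#' usual mean difference over the root average variance.
#'
#' @param m1,m2 [moment_pair()] objects (or lists with `mean` and `variance`)
#'   for groups 1 and 2.
#' @param n1,n2 Per-group sample sizes (>= 1).
#' @return The standardized mean difference (group 1 minus group 2).
#' @examples
#' standardized_mean_difference(moment_pair(1, 1), moment_pair(0, 1), 50, 50)
#' @export
standardized_mean_difference <- function(m1, m2, n1, n2) {
  stopifnot(n1 >= 1, n2 >= 1)
  v1 <- m1$variance; v2 <- m2$variance
  denom2 <- (n2 * v1 + n1 * v2) / (n1 + n2)
  if (denom2 <= 0) {
    stop("degenerate input: both variances are zero", call. = FALSE)
  }
  (m1$mean - m2$mean) / sqrt(denom2)
}

#' Two-group design realizing a target rectified-normal effect size
#'
#' Holds per-group sample sizes and the latent shift `delta` applied to
#' group 2's latent mean so that the standardized mean difference computed
#' from the two groups' exact rectified-normal moments equals `target_es`.
#' The constructor verifies the round trip.
#'
#' @param n1,n2 Per-group sample sizes.
#' @param delta Latent mean shift of group 2 relative to the group-1
#'   baseline.
#' @param target_es The rectified-normal-scale standardized mean difference
#'   this delta realizes (group 2 minus group 1, so a positive shift gives a
#'   positive effect size).
#' @param spec_base Group-1 latent specification (default centred standard).
#' @return An object of class `two_group_design`.
#' @seealso [calibrate_shift()] which constructs one from a target.
#' @export
two_group_design <- function(n1, n2, delta, target_es, spec_base = rtn_spec()) {
  stopifnot(n1 >= 1, n2 >= 1, is.finite(delta), is.finite(target_es))
  spec2 <- rtn_spec(spec_base$mu + delta, spec_base$sigma,
                    spec_base$lower, spec_base$upper)
  realized <- standardized_mean_difference(
    rtn_moments(spec2), rtn_moments(spec_base), n1, n2
  )
  if (abs(realized - target_es) > 1e-6) {
    stop(sprintf(
      "delta = %g realizes RTN effect size %.8f, not the stated %.8f",
      delta, realized, target_es
    ), call. = FALSE)
  }
  structure(
    list(n1 = as.integer(n1), n2 = as.integer(n2), delta = delta,
         target_es = target_es, spec_base = spec_base),
    class = "two_group_design"
  )
}

#' @export
print.two_group_design <- function(x, ...) {
  cat(sprintf(
    "<two_group_design> n = (%d, %d), latent shift %.6g -> RTN effect size %.4g\n",
    x$n1, x$n2, x$delta, x$target_es
  ))
  invisible(x)
}

#' Calibrate the latent shift for a target rectified-normal effect size
#'
#' Finds the group-2 latent mean shift whose exact clipped-normal moments
#' give the requested standardized mean difference on the rectified-normal
#' scale. The shift-to-effect-size map is continuous and strictly monotone,
#' so a derivative-free bracketing bisection is used: the bracket starts at
#' `[0, 1]` (or its mirror for negative targets), doubles until it straddles
#' the root, then bisects until the residual is below `tol`.
#'
#' @param target_es Target effect size on the rectified-normal scale.
#' @param spec_base Group-1 latent specification.
#' @param n1,n2 Per-group sample sizes (affect the effect size only through
#'   the variance weights; with `n1 == n2` the calibration is sample-size
#'   free).
#' @param tol Convergence tolerance on the effect-size residual.
#' @return A [two_group_design()].
#' @examples
#' calibrate_shift(0.2, n1 = 30, n2 = 30)
#' @export
calibrate_shift <- function(target_es, spec_base = rtn_spec(),
                            n1 = 100, n2 = 100, tol = 1e-8) {
  stopifnot(is.finite(target_es))
  es_of <- function(delta) {
    spec2 <- rtn_spec(spec_base$mu + delta, spec_base$sigma,
                      spec_base$lower, spec_base$upper)
    standardized_mean_difference(rtn_moments(spec2), rtn_moments(spec_base),
                                 n1, n2)
  }
  if (target_es == 0) {
    return(two_group_design(n1, n2, 0, 0, spec_base))
  }
  sgn <- sign(target_es)
  lo <- 0; hi <- sgn
  it <- 0L
  while (sgn * (es_of(hi) - target_es) < 0) {
    lo <- hi; hi <- 2 * hi
    it <- it + 1L
    if (it > 60L) stop("bracket expansion failed to straddle the target",
                       call. = FALSE)
  }
  if (sgn < 0) { tmp <- lo; lo <- hi; hi <- tmp }  # keep lo < hi
  mid <- (lo + hi) / 2
  for (i in seq_len(200L)) {
    mid <- (lo + hi) / 2
    f <- es_of(mid) - target_es
    if (abs(f) <= tol) break
    if (f < 0) lo <- mid else hi <- mid
    if (i == 200L) stop("bisection did not converge", call. = FALSE)
  }
  two_group_design(n1, n2, mid, target_es, spec_base)
}

#' Effect-size attenuation ratio of a Likert transform
#'
#' Ratio of the standardized mean difference computed from the exact moments
#' of the discretized (Likert) variable in the two groups to the
#' rectified-normal-scale effect size the design was calibrated to. Values
#' below 1 quantify the information lost by discretization; the ratio
#' approaches 1 as the number of scale points grows.
#'
#' @param scheme A [likert_scheme()].
#' @param design A calibrated [two_group_design()] with nonzero
#'   `target_es`.
#' @param spec_base Group-1 latent specification (defaults to the one stored
#'   in the design).
#' @return The dimensionless attenuation ratio.
#' @examples
#' d <- calibrate_shift(0.2)
#' effect_size_ratio(likert_scheme(2), d)  # about 0.80
#' effect_size_ratio(likert_scheme(5), d)  # about 0.96
#' @export
effect_size_ratio <- function(scheme, design, spec_base = design$spec_base) {
  stopifnot(inherits(scheme, "likert_scheme"), inherits(design, "two_group_design"))
  if (design$target_es == 0) {
    stop("attenuation ratio is undefined at zero effect size", call. = FALSE)
  }
  spec2 <- rtn_spec(spec_base$mu + design$delta, spec_base$sigma,
                    spec_base$lower, spec_base$upper)
  d_lks <- standardized_mean_difference(
    lks_moments(spec2, scheme), lks_moments(spec_base, scheme),
    design$n1, design$n2
  )
  d_lks / design$target_es
}
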