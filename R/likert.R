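#' Equal-interval Likert discretization scheme
#'
#' Defines a k-point Likert variable as an equal-width partition of a
#' rectified-normal range: the interval `[lower, upper]` is divided into `k`
#' bins of identical width and bin `j` is mapped to integer level `j`.
#'
#' @param k Number of scale points (integer >= 2).
#' @param lower,upper Range being partitioned; must match the limits of the
#'   latent [rtn_spec()] the scheme is applied to.
#' @return An object of class `likert_scheme` with elements `k`, `edges`
#'   (length `k + 1`), and `levels` (`1:k`).
#' @examples
#' likert_scheme(5)
#' @export
likert_scheme <- function(k, lower = -2, upper = 2) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k))
  if (k < 2 || k != round(k)) stop("`k` must be an integer >= 2", call. = FALSE)
  if (lower >= upper) stop("`lower` must be less than `upper`", call. = FALSE)
  k <- as.integer(k)
  structure(
    list(k = k, edges = seq(lower, upper, length.out = k + 1L), levels = seq_len(k)),
    class = "likert_scheme"
  )
}

#' @export
print.likert_scheme <- function(x, ...) {
  cat(sprintf("<likert_scheme> %d points on [%g, %g], bin width %g\n",
              x$k, x$edges[1], x$edges[x$k + 1L], diff(x$edges[1:2])))
  invisible(x)
}

#' Discretize rectified-normal values into Likert levels
#'
#' Maps each value to its bin with intervals half-open on the left,
#' `(e_{j-1}, e_j] -> j`; the lower limit itself maps to level 1. Interior
#' edges carry zero probability under a continuous latent density, so the
#' open/closed convention is statistically immaterial but fixed for
#' determinism.
#'
#' @param x Numeric vector with all values in `[lower, upper]`.
#' @param scheme A [likert_scheme()].
#' @return Integer vector of levels in `1:k`.
#' @examples
#' discretize(c(-2, -0.5, 0.1, 2), likert_scheme(4))
#' @export
discretize <- function(x, scheme) {
  stopifnot(inherits(scheme, "likert_scheme"), is.numeric(x))
  e <- scheme$edges
  lo <- e[1L]; hi <- e[length(e)]
  if (any(x < lo | x > hi, na.rm = FALSE)) {
    stop("values outside the scheme range [", lo, ", ", hi, "]", call. = FALSE)
  }
  lev <- findInterval(x, e, left.open = TRUE)
  lev[lev == 0L] <- 1L   # x == lower belongs to the first bin
  as.integer(lev)
}

#' Exact level probabilities of a discretized rectified-normal variable
#'
#' Because clipping moves all mass beyond a limit onto that limit, and the
#' limits are the outermost bin edges, the boundary masses fold into the two
#' extreme levels. The probabilities are therefore plain normal-CDF
#' differences with open tails at both ends:
#' `P(level 1) = Phi((e_1 - mu)/sigma)` and
#' `P(level k) = 1 - Phi((e_{k-1} - mu)/sigma)`.
#'
#' @param spec An [rtn_spec()]; its limits must equal the scheme's range.
#' @param scheme A [likert_scheme()].
#' @return Numeric probability vector of length `k`, summing to 1.
#' @examples
#' likert_probabilities(rtn_spec(), likert_scheme(4))
#' @export
likert_probabilities <- function(spec, scheme) {
  stopifnot(inherits(spec, "rtn_spec"), inherits(scheme, "likert_scheme"))
  e <- scheme$edges
  if (e[1L] != spec$lower || e[length(e)] != spec$upper) {
    stop("scheme range must equal the rtn_spec limits", call. = FALSE)
  }
  z <- (e - spec$mu) / spec$sigma
  cum <- stats::pnorm(z)
  cum[1L] <- 0
  cum[length(cum)] <- 1
  p <- diff(cum)
  p / sum(p)
}

#' Exact mean and variance of a Likert-transformed variable
#'
#' Moments of the integer-level variable under the exact level probabilities,
#' `mean = sum(j * p_j)` and `variance = sum(j^2 * p_j) - mean^2`. Used to
#' compute attenuation of standardized effect sizes without simulation noise.
#'
#' @inheritParams likert_probabilities
#' @return A [moment_pair()].
#' @examples
#' lks_moments(rtn_spec(), likert_scheme(2)) # mean 1.5, variance 0.25
#' @export
lks_moments <- function(spec, scheme) {
  p <- likert_probabilities(spec, scheme)
  j <- scheme$levels
  m <- sum(j * p)
  moment_pair(m, max(sum(j^2 * p) - m^2, 0))
}
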