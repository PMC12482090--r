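#' Exchangeably correlated multivariate latent specification
#'
#' Describes `p` latent normal variables with unit scale, the given means,
#' and a single common pairwise correlation `rho` (exchangeable structure).
#' `rho = 1` duplicates a single variable; `rho = 0` gives independence.
#' Negative exchangeable correlations are outside the supported grid.
#'
#' @param p Number of variables (integer >= 1).
#' @param rho Common pairwise latent correlation in `[0, 1]`.
#' @param mu Latent means; scalar (recycled) or length-`p` vector.
#' @return An object of class `mv_spec`.
#' @export
mv_spec <- function(p, rho = 0, mu = 0) {
  stopifnot(is.numeric(p), length(p) == 1L, p >= 1, p == round(p),
            is.numeric(rho), length(rho) == 1L)
  if (rho < 0 || rho > 1) stop("`rho` must be in [0, 1]", call. = FALSE)
  p <- as.integer(p)
  if (length(mu) == 1L) mu <- rep(mu, p)
  if (length(mu) != p) stop("`mu` must have length 1 or p", call. = FALSE)
  structure(list(p = p, rho = rho, mu = mu), class = "mv_spec")
}

#' @export
print.mv_spec <- function(x, ...) {
  cat(sprintf("<mv_spec> p = %d latent normals, exchangeable rho = %g\n",
              x$p, x$rho))
  invisible(x)
}

#' Sample exchangeably correlated latent normals
#'
#' Uses the one-factor construction
#' `X_j = mu_j + sqrt(rho) * C + sqrt(1 - rho) * U_j`
#' with a single shared standard normal `C` per row and independent unique
#' components `U_j`. This realizes the exchangeable correlation exactly for
#' any `rho` in `[0, 1]`, including the degenerate endpoint `rho = 1` where
#' all centred columns coincide.
#'
#' @param spec An [mv_spec()].
#' @param n Number of rows to draw.
#' @return An `n x p` numeric matrix.
#' @examples
#' set.seed(1)
#' round(cor(exchangeable_latent_sample(mv_spec(3, 0.5), 1e4)), 2)
#' @export
exchangeable_latent_sample <- function(spec, n) {
  stopifnot(inherits(spec, "mv_spec"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  n <- as.integer(n)
  common <- stats::rnorm(n)
  a <- sqrt(spec$rho); b <- sqrt(1 - spec$rho)
  x <- matrix(stats::rnorm(n * spec$p), n, spec$p)
  x <- a * common + b * x
  sweep(x, 2L, spec$mu, `+`)
}

#' Coupled latent / rectified / Likert dataset
#'
#' Draws one latent matrix and derives every requested variable type from
#' the SAME draws: the rectified matrix is the elementwise clip of the
#' latent, and each Likert matrix is the discretization of the rectified
#' one under its scheme. Coupling the types within a replicate mirrors the
#' conversion of one underlying response into all scale types and reduces
#' Monte Carlo variance when types are compared.
#'
#' @param spec An [mv_spec()].
#' @param schemes List of [likert_scheme()] objects (one per Likert type).
#' @param n Number of rows.
#' @param spec_rtn An [rtn_spec()] carrying the clipping limits (its mean
#'   and scale are ignored; the latent means come from `spec`).
#' @return An object of class `coupled_dataset` with elements `latent`,
#'   `rtn`, and `lks` (a list of integer matrices named by their point
#'   count).
#' @export
make_coupled_dataset <- function(spec, schemes, n, spec_rtn = rtn_spec()) {
  stopifnot(inherits(spec, "mv_spec"))
  if (inherits(schemes, "likert_scheme")) schemes <- list(schemes)
  stopifnot(all(vapply(schemes, inherits, logical(1), "likert_scheme")))
  latent <- exchangeable_latent_sample(spec, n)
  rtn <- pmin(pmax(latent, spec_rtn$lower), spec_rtn$upper)
  lks <- lapply(schemes, function(s) {
    matrix(discretize(as.vector(rtn), s), nrow(rtn), ncol(rtn))
  })
  names(lks) <- vapply(schemes, function(s) as.character(s$k), character(1))
  structure(list(latent = latent, rtn = rtn, lks = lks),
            class = "coupled_dataset")
}

#' @export
print.coupled_dataset <- function(x, ...) {
  cat(sprintf("<coupled_dataset> %d x %d; Likert types: %s\n",
              nrow(x$latent), ncol(x$latent),
              paste(names(x$lks), collapse = ", ")))
  invisible(x)
}

#' Two-group coupled dataset under a calibrated design
#'
#' Group 1 is drawn at the latent baseline (mean 0 in every coordinate);
#' group 2 applies the design's calibrated shift to EVERY latent mean, so
#' each marginal attains the target rectified-normal effect size.
#'
#' @param design A [two_group_design()].
#' @param spec0 An [mv_spec()] describing the group-1 structure (its means
#'   are used as the baseline).
#' @param schemes List of [likert_scheme()] objects.
#' @return List with elements `group1` and `group2`, each a
#'   [make_coupled_dataset()] result with `n1` / `n2` rows.
#' @export
two_group_dataset <- function(design, spec0, schemes) {
  stopifnot(inherits(design, "two_group_design"), inherits(spec0, "mv_spec"))
  spec1 <- spec0
  spec2 <- mv_spec(spec0$p, spec0$rho, spec0$mu + design$delta)
  base <- design$spec_base
  list(
    group1 = make_coupled_dataset(spec1, schemes, design$n1, base),
    group2 = make_coupled_dataset(spec2, schemes, design$n2, base)
  )
}
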