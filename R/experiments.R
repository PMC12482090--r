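#' Simulation configuration
#'
#' Holds the experiment grids, replication count, significance level, and
#' master seed shared by the simulation drivers. The defaults are the study
#' conditions of the package's reference simulation design: effect sizes
#' {0, 0.2, 0.5}, per-group sample sizes {30, 50, 100, 300, 500}, 2- to
#' 7-point Likert scales, exchangeable correlations {0, 0.25, 0.5, 0.75, 1},
#' merge counts {2, 3, 5, 10}, explanatory-variable counts {1, 2, 3, 5, 10},
#' and 10,000 Monte Carlo replicates per cell (binomial SE at most 0.5
#' percentage points).
#'
#' @param effect_sizes Rectified-normal-scale standardized mean differences.
#' @param sample_sizes Per-group sample sizes for the single-response grid.
#' @param likert_points Numbers of scale points.
#' @param rhos Exchangeable latent pairwise correlations.
#' @param merge_counts Numbers of variables merged into a total score.
#' @param n_explanatory Numbers of explanatory variables in the regression
#'   grid.
#' @param n_reps Monte Carlo replicates per cell.
#' @param alpha Two-sided significance level.
#' @param seed Master seed; per-cell streams are derived from it so results
#'   do not depend on grid order.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(effect_sizes = c(0, 0.2, 0.5),
                       sample_sizes = c(30, 50, 100, 300, 500),
                       likert_points = 2:7,
                       rhos = c(0, 0.25, 0.5, 0.75, 1),
                       merge_counts = c(2, 3, 5, 10),
                       n_explanatory = c(1, 2, 3, 5, 10),
                       n_reps = 10000,
                       alpha = 0.05,
                       seed = 1) {
  stopifnot(n_reps >= 1, alpha > 0, alpha < 1,
            all(likert_points >= 2), all(rhos >= 0), all(rhos <= 1))
  structure(
    list(effect_sizes = effect_sizes, sample_sizes = as.integer(sample_sizes),
         likert_points = as.integer(likert_points), rhos = rhos,
         merge_counts = as.integer(merge_counts),
         n_explanatory = as.integer(n_explanatory),
         n_reps = as.integer(n_reps), alpha = alpha,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  effect sizes :", paste(x$effect_sizes, collapse = ", "), "\n")
  cat("  n per group  :", paste(x$sample_sizes, collapse = ", "), "\n")
  cat("  scale points :", paste(x$likert_points, collapse = ", "), "\n")
  cat("  correlations :", paste(x$rhos, collapse = ", "), "\n")
  cat("  merge counts :", paste(x$merge_counts, collapse = ", "), "\n")
  cat("  explanatory  :", paste(x$n_explanatory, collapse = ", "), "\n")
  cat(sprintf("  %d replicates, alpha = %g, seed = %d\n",
              x$n_reps, x$alpha, x$seed))
  invisible(x)
}

# Deterministic per-cell seed: a polynomial string hash of the experiment
# name and cell label folded with the master seed, kept below 2^31 so the
# grid is reorder- and parallelization-invariant.
derive_seed <- function(seed, experiment, cell) {
  s <- paste(experiment, cell, sep = "::")
  h <- 0
  for (code in utf8ToInt(s)) h <- (h * 31 + code) %% 2147483563
  as.integer((h + (seed %% 2147483563) * 1009) %% 2147483562 + 1)
}

type_label <- function(k) if (is.na(k)) "RTN" else sprintf("%d-pt", k)

parse_type <- function(type) {
  if (is.numeric(type)) return(as.integer(type))
  if (identical(toupper(type), "RTN")) return(NA_integer_)
  k <- suppressWarnings(as.integer(sub("-pt.*$", "", type)))
  if (is.na(k)) stop("unknown variable type: ", type, call. = FALSE)
  k
}

clip_mat <- function(x, spec) pmin(pmax(x, spec$lower), spec$upper)

# transform a clipped matrix into the requested type (NA = keep RTN scale)
type_transform <- function(rtn, k, spec_base) {
  if (is.na(k)) return(rtn)
  scheme <- likert_scheme(k, spec_base$lower, spec_base$upper)
  matrix(discretize(as.vector(rtn), scheme), nrow(rtn), ncol(rtn))
}

# per-replicate standardized mean difference (equal-n weighting handled by
# standardized_mean_difference's formula), averaged over replicate columns
mean_smd_cols <- function(x1, x2) {
  n1 <- nrow(x1); n2 <- nrow(x2)
  m1 <- colMeans(x1); m2 <- colMeans(x2)
  v1 <- (colSums(x1 * x1) - n1 * m1^2) / (n1 - 1)
  v2 <- (colSums(x2 * x2) - n2 * m2^2) / (n2 - 1)
  denom2 <- (n2 * v1 + n1 * v2) / (n1 + n2)
  ok <- denom2 > 0
  mean((m2[ok] - m1[ok]) / sqrt(denom2[ok]))
}

#' Type-1 error and power of the two-sample t-test across variable types
#'
#' For every combination of effect size, per-group sample size, and variable
#' type (rectified-normal plus each Likert point count), calibrates the
#' group-2 latent shift on the rectified-normal scale, draws coupled
#' two-group data (every type derived from the same latent draws within a
#' replicate), applies the Welch t-test to the chosen type, and reports the
#' percent of replicates with p below `alpha`.
#'
#' @param cfg A [sim_config()].
#' @param spec_base Baseline latent specification.
#' @return A data frame with one row per cell: `effect_size`, `type`, `k`,
#'   `n_per_group`, `power` (percent), `se` (percent), `ci_low`, `ci_high`,
#'   `n_reps`, `n_degenerate`.
#' @examples
#' cfg <- sim_config(effect_sizes = 0.2, sample_sizes = 30,
#'                   likert_points = 2, n_reps = 200)
#' run_single_response_power(cfg)
#' @export
run_single_response_power <- function(cfg = sim_config(), spec_base = rtn_spec()) {
  stopifnot(inherits(cfg, "sim_config"))
  types <- c(NA_integer_, cfg$likert_points)
  out <- list()
  for (es in cfg$effect_sizes) {
    delta <- if (es == 0) 0 else calibrate_shift(es, spec_base, 100, 100)$delta
    for (n in cfg$sample_sizes) {
      set.seed(derive_seed(cfg$seed, "single_response",
                           sprintf("es=%g;n=%d", es, n)))
      l1 <- matrix(stats::rnorm(n * cfg$n_reps), n)
      l2 <- matrix(stats::rnorm(n * cfg$n_reps), n) + delta
      r1 <- clip_mat(l1, spec_base)
      r2 <- clip_mat(l2, spec_base)
      for (k in types) {
        x1 <- type_transform(r1, k, spec_base)
        x2 <- type_transform(r2, k, spec_base)
        w <- welch_p_cols(x1, x2)
        est <- proportion_estimate(sum(w$p < cfg$alpha), cfg$n_reps)
        out[[length(out) + 1L]] <- data.frame(
          effect_size = es, type = type_label(k), k = k, n_per_group = n,
          power = 100 * est$p_hat, se = 100 * est$se,
          ci_low = 100 * est$ci_low, ci_high = 100 * est$ci_high,
          n_reps = cfg$n_reps, n_degenerate = w$n_degenerate
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Required per-group sample size for a target power
#'
#' Inverts the two-sample normal-approximation power formula on the
#' attenuated effect size of the requested variable type:
#' `n = ceiling(2 * (z_{1-alpha/2} + z_{power})^2 / d^2)` with
#' `d = es_rtn * attenuation ratio`. When `refine = TRUE` the analytic
#' answer seeds a local simulated search (step 1, Welch test at
#' `cfg$n_reps` replicates per candidate) for simulation-grade output.
#'
#' @param type `"RTN"`, a point count, or a label like `"2-pt"`.
#' @param es_rtn Effect size on the rectified-normal scale (> 0).
#' @param power_target Target power in (0, 1).
#' @param cfg A [sim_config()] (supplies `alpha`, `n_reps`, `seed`).
#' @param refine Refine the analytic inversion by local simulation.
#' @param spec_base Baseline latent specification.
#' @return Required per-group sample size (integer).
#' @examples
#' required_n_for_power("RTN", 0.1)   # about 1570
#' required_n_for_power(2, 0.1)       # about 2442
#' @export
required_n_for_power <- function(type, es_rtn, power_target = 0.8,
                                 cfg = sim_config(), refine = FALSE,
                                 spec_base = rtn_spec()) {
  stopifnot(es_rtn > 0, power_target > 0, power_target < 1)
  k <- parse_type(type)
  ratio <- if (is.na(k)) 1 else {
    effect_size_ratio(likert_scheme(k, spec_base$lower, spec_base$upper),
                      calibrate_shift(es_rtn, spec_base, 100, 100), spec_base)
  }
  d <- es_rtn * ratio
  za <- stats::qnorm(1 - cfg$alpha / 2)
  zb <- stats::qnorm(power_target)
  n <- ceiling(2 * (za + zb)^2 / d^2)
  if (!refine) return(as.integer(n))

  delta <- calibrate_shift(es_rtn, spec_base, 100, 100)$delta
  sim_power <- function(n) {
    set.seed(derive_seed(cfg$seed, "required_n",
                         sprintf("type=%s;es=%g;n=%d", type_label(k), es_rtn, n)))
    l1 <- matrix(stats::rnorm(n * cfg$n_reps), n)
    l2 <- matrix(stats::rnorm(n * cfg$n_reps), n) + delta
    x1 <- type_transform(clip_mat(l1, spec_base), k, spec_base)
    x2 <- type_transform(clip_mat(l2, spec_base), k, spec_base)
    mean(welch_p_cols(x1, x2)$p < cfg$alpha)
  }
  for (i in seq_len(25L)) {
    if (sim_power(n) >= power_target) {
      if (n == 1L || sim_power(n - 1L) < power_target) break
      n <- n - 1L
    } else {
      n <- n + 1L
    }
  }
  as.integer(n)
}

#' Power of the t-test on merged (total-score) correlated variables
#'
#' Reproduces the merged-variable experiment: per replicate, `p` latent
#' variables with exchangeable correlation `rho` are drawn for each group
#' (group 2 shifted in every coordinate to the per-variable
#' rectified-normal effect size `es`), converted to each variable type from
#' the same draws, summed into a total score, and compared with the Welch
#' t-test. For Likert cells the required per-group sample size to match the
#' same-cell rectified-normal power is reported, obtained from the ratio of
#' the two merged-score empirical effect sizes
#' (`n_req = ceiling(n * (d_rtn / d_lks)^2)`).
#'
#' @param cfg A [sim_config()]; uses `merge_counts`, `rhos`,
#'   `likert_points`, `n_reps`, `alpha`, `seed`.
#' @param es Per-variable rectified-normal effect size.
#' @param n_per_group Per-group sample size.
#' @param spec_base Baseline latent specification.
#' @return Data frame with one row per (merge count, rho, type) cell,
#'   including `required_n` (NA for the rectified-normal reference).
#' @export
run_merged_power <- function(cfg = sim_config(), es = 0.2, n_per_group = 100,
                             spec_base = rtn_spec()) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- as.integer(n_per_group)
  delta <- calibrate_shift(es, spec_base, n, n)$delta
  types <- c(NA_integer_, cfg$likert_points)
  p_max <- max(cfg$merge_counts)
  out <- list()
  for (rho in cfg$rhos) {
    set.seed(derive_seed(cfg$seed, "merged_power", sprintf("rho=%g", rho)))
    a <- sqrt(rho); b <- sqrt(1 - rho)
    c1 <- matrix(stats::rnorm(n * cfg$n_reps), n)
    c2 <- matrix(stats::rnorm(n * cfg$n_reps), n)
    s1 <- s2 <- stats::setNames(vector("list", length(types)),
                                vapply(types, type_label, character(1)))
    for (tl in names(s1)) { s1[[tl]] <- 0; s2[[tl]] <- 0 }
    for (j in seq_len(p_max)) {
      l1 <- a * c1 + b * matrix(stats::rnorm(n * cfg$n_reps), n)
      l2 <- a * c2 + b * matrix(stats::rnorm(n * cfg$n_reps), n) + delta
      r1 <- clip_mat(l1, spec_base)
      r2 <- clip_mat(l2, spec_base)
      for (k in types) {
        tl <- type_label(k)
        s1[[tl]] <- s1[[tl]] + type_transform(r1, k, spec_base)
        s2[[tl]] <- s2[[tl]] + type_transform(r2, k, spec_base)
      }
      if (j %in% cfg$merge_counts) {
        d_rtn <- mean_smd_cols(s1[["RTN"]], s2[["RTN"]])
        for (k in types) {
          tl <- type_label(k)
          w <- welch_p_cols(s1[[tl]], s2[[tl]])
          est <- proportion_estimate(sum(w$p < cfg$alpha), cfg$n_reps)
          req <- if (is.na(k)) NA_integer_ else {
            d_lks <- mean_smd_cols(s1[[tl]], s2[[tl]])
            as.integer(ceiling(n * (d_rtn / d_lks)^2))
          }
          out[[length(out) + 1L]] <- data.frame(
            merge_count = j, rho = rho, type = tl, k = k,
            power = 100 * est$p_hat, se = 100 * est$se,
            ci_low = 100 * est$ci_low, ci_high = 100 * est$ci_high,
            required_n = req, n_reps = cfg$n_reps,
            n_degenerate = w$n_degenerate
          )
        }
      }
    }
  }
  do.call(rbind, out)
}

#' Preservation of correlation structure under discretization (GFI, SRMR)
#'
#' Per replicate, draws one coupled dataset of `p` exchangeably correlated
#' latent variables, computes the sample correlation matrix of the
#' rectified columns (reference `A`) and of each Likert transform
#' (comparison `B`), and summarizes [gfi()] and [srmr()] over replicates.
#' Replicates where either correlation matrix is undefined (a constant
#' column) or where `A` equals the identity are dropped and counted.
#'
#' @param cfg A [sim_config()]; correlations of exactly 1 are excluded from
#'   the grid (the reference matrix would be singular against its own
#'   duplicate).
#' @param n Rows per dataset.
#' @param spec_base Baseline latent specification.
#' @return Data frame with one row per (p, rho, k) cell: mean and SE of GFI
#'   and SRMR, replicates used, and replicates dropped.
#' @export
run_correlation_similarity <- function(cfg = sim_config(), n = 200,
                                       spec_base = rtn_spec()) {
  stopifnot(inherits(cfg, "sim_config"))
  rhos <- cfg$rhos[cfg$rhos < 1]
  schemes <- lapply(cfg$likert_points, likert_scheme,
                    lower = spec_base$lower, upper = spec_base$upper)
  out <- list()
  for (p in cfg$merge_counts) {
    for (rho in rhos) {
      set.seed(derive_seed(cfg$seed, "correlation_similarity",
                           sprintf("p=%d;rho=%g", p, rho)))
      spec <- mv_spec(p, rho)
      nk <- length(schemes)
      g_sum <- g_sq <- s_sum <- s_sq <- used <- dropped <- numeric(nk)
      for (r in seq_len(cfg$n_reps)) {
        ds <- make_coupled_dataset(spec, schemes, n, spec_base)
        A <- stats::cor(ds$rtn)
        a_bad <- anyNA(A) || all(abs(A - diag(p)) < .Machine$double.eps)
        for (i in seq_len(nk)) {
          B <- suppressWarnings(stats::cor(ds$lks[[i]]))
          if (a_bad || anyNA(B)) { dropped[i] <- dropped[i] + 1; next }
          g <- gfi(A, B); s <- srmr(A, B)
          g_sum[i] <- g_sum[i] + g; g_sq[i] <- g_sq[i] + g^2
          s_sum[i] <- s_sum[i] + s; s_sq[i] <- s_sq[i] + s^2
          used[i] <- used[i] + 1
        }
      }
      for (i in seq_len(nk)) {
        m_g <- g_sum[i] / used[i]; m_s <- s_sum[i] / used[i]
        out[[length(out) + 1L]] <- data.frame(
          p = p, rho = rho, type = type_label(cfg$likert_points[i]),
          k = cfg$likert_points[i],
          mean_gfi = m_g,
          se_gfi = sqrt(max(g_sq[i] / used[i] - m_g^2, 0) / used[i]),
          mean_srmr = m_s,
          se_srmr = sqrt(max(s_sq[i] / used[i] - m_s^2, 0) / used[i]),
          n_reps_used = used[i], n_dropped = dropped[i]
        )
      }
    }
  }
  do.call(rbind, out)
}

# analytic power of the overall F-test at effect size f2 = R^2/(1-R^2)
ncf_power <- function(f2, n, q, alpha) {
  df2 <- n - q - 1
  if (df2 < 1) return(0)
  crit <- stats::qf(1 - alpha, q, df2)
  stats::pf(crit, q, df2, ncp = n * f2, lower.tail = FALSE)
}

#' Power of the overall regression F-test across variable types
#'
#' Per replicate, draws one coupled dataset of `max(q) + 1` exchangeably
#' correlated variables (latent pairwise correlation `rho`), assigns the
#' first column as the response in the response type and the next `q`
#' columns as explanatory variables in the explanatory type, and counts
#' overall-F rejections. All cells share the replicate's draws, which
#' stabilizes comparisons across types and `q`. For Likert-explanatory
#' cells, the required total sample size to match the power of the
#' rectified-normal-explanatory cell with the same response type is
#' reported, from noncentral-F inversion on each cell's mean empirical
#' `f^2 = R^2 / (1 - R^2)` (searched on an even-n grid).
#'
#' @param cfg A [sim_config()]; `n_explanatory` supplies the q grid.
#' @param n Rows per dataset.
#' @param rho Common latent pairwise correlation among all variables.
#' @param response_types,explanatory_types Types to cross (defaults:
#'   rectified-normal plus Likert points up to 5).
#' @param spec_base Baseline latent specification.
#' @return Data frame with one row per (response type, explanatory type, q)
#'   cell, including `required_n` (total n; NA for the
#'   rectified-normal-explanatory reference cells).
#' @export
run_regression_power <- function(cfg = sim_config(), n = 200, rho = 0.2,
                                 response_types = NULL,
                                 explanatory_types = NULL,
                                 spec_base = rtn_spec()) {
  stopifnot(inherits(cfg, "sim_config"))
  pts <- cfg$likert_points[cfg$likert_points <= 5]
  if (is.null(response_types)) response_types <- c(NA_integer_, pts)
  else response_types <- vapply(response_types, parse_type, integer(1))
  if (is.null(explanatory_types)) explanatory_types <- c(NA_integer_, pts)
  else explanatory_types <- vapply(explanatory_types, parse_type, integer(1))
  qs <- sort(cfg$n_explanatory)
  p_all <- max(qs) + 1L
  ks <- sort(unique(stats::na.omit(c(response_types, explanatory_types))))
  spec <- mv_spec(p_all, rho)

  dims <- c(length(response_types), length(explanatory_types), length(qs))
  rej <- array(0, dims)
  r2_sum <- array(0, dims)
  set.seed(derive_seed(cfg$seed, "regression_power",
                       sprintf("n=%d;rho=%g", n, rho)))
  for (rep in seq_len(cfg$n_reps)) {
    latent <- exchangeable_latent_sample(spec, n)
    rtn <- clip_mat(latent, spec_base)
    mats <- list(RTN = rtn)
    for (k in ks) {
      mats[[type_label(k)]] <- type_transform(rtn, k, spec_base)
    }
    for (ri in seq_along(response_types)) {
      y <- mats[[type_label(response_types[ri])]][, 1L]
      for (ei in seq_along(explanatory_types)) {
        xm <- mats[[type_label(explanatory_types[ei])]]
        for (qi in seq_along(qs)) {
          q <- qs[qi]
          X <- xm[, 2:(q + 1L), drop = FALSE]
          fit <- stats::lm.fit(cbind(1, X), y)
          rank <- fit$rank
          if (rank < 2L) next
          rss <- sum(fit$residuals^2)
          tss <- sum((y - mean(y))^2)
          r2 <- 1 - rss / tss
          df2 <- n - rank
          fstat <- ((tss - rss) / (rank - 1L)) / (rss / df2)
          pval <- stats::pf(fstat, rank - 1L, df2, lower.tail = FALSE)
          if (pval < cfg$alpha) rej[ri, ei, qi] <- rej[ri, ei, qi] + 1
          r2_sum[ri, ei, qi] <- r2_sum[ri, ei, qi] + r2
        }
      }
    }
  }

  out <- list()
  rtn_ei <- which(is.na(explanatory_types))
  for (ri in seq_along(response_types)) {
    for (ei in seq_along(explanatory_types)) {
      for (qi in seq_along(qs)) {
        q <- qs[qi]
        est <- proportion_estimate(rej[ri, ei, qi], cfg$n_reps)
        req <- NA_integer_
        if (!is.na(explanatory_types[ei]) && length(rtn_ei) == 1L) {
          f2_ref <- local({
            m <- r2_sum[ri, rtn_ei, qi] / cfg$n_reps; m / (1 - m)
          })
          f2_cell <- local({
            m <- r2_sum[ri, ei, qi] / cfg$n_reps; m / (1 - m)
          })
          target <- ncf_power(f2_ref, n, q, cfg$alpha)
          n_try <- q + 2L + (q %% 2L)
          while (ncf_power(f2_cell, n_try, q, cfg$alpha) < target &&
                 n_try < 100000L) {
            n_try <- n_try + 2L
          }
          req <- n_try
        }
        out[[length(out) + 1L]] <- data.frame(
          response_type = type_label(response_types[ri]),
          explanatory_type = type_label(explanatory_types[ei]),
          q = q, power = 100 * est$p_hat, se = 100 * est$se,
          ci_low = 100 * est$ci_low, ci_high = 100 * est$ci_high,
          required_n = req, n_reps = cfg$n_reps
        )
      }
    }
  }
  do.call(rbind, out)
}

#' Effect-size attenuation curves across the effect-size grid
#'
#' Computes the analytic attenuation ratio of every Likert type at every
#' effect size (see [effect_size_ratio()]); optionally adds a simulated
#' ratio (mean estimated Likert-scale effect size over replicates divided
#' by the nominal rectified-normal effect size) as a Monte Carlo check.
#'
#' @param cfg A [sim_config()].
#' @param es_grid Positive effect sizes (default 0.1 to 0.5).
#' @param simulate Also estimate the ratios by simulation at
#'   `cfg$n_reps` replicates with `n = 100` per group.
#' @param spec_base Baseline latent specification.
#' @return Data frame with columns `effect_size`, `type`, `k`, `ratio`
#'   (and `ratio_sim` when simulated).
#' @examples
#' run_effect_size_curve(es_grid = c(0.1, 0.3))
#' @export
run_effect_size_curve <- function(cfg = sim_config(),
                                  es_grid = seq(0.1, 0.5, by = 0.1),
                                  simulate = FALSE, spec_base = rtn_spec()) {
  stopifnot(all(es_grid > 0))
  types <- c(NA_integer_, cfg$likert_points)
  out <- list()
  for (es in es_grid) {
    design <- calibrate_shift(es, spec_base, 100, 100)
    for (k in types) {
      ratio <- if (is.na(k)) 1 else {
        effect_size_ratio(likert_scheme(k, spec_base$lower, spec_base$upper),
                          design, spec_base)
      }
      row <- data.frame(effect_size = es, type = type_label(k), k = k,
                        ratio = ratio)
      if (simulate) {
        n <- 100L
        set.seed(derive_seed(cfg$seed, "effect_size_curve",
                             sprintf("es=%g;k=%s", es, type_label(k))))
        l1 <- matrix(stats::rnorm(n * cfg$n_reps), n)
        l2 <- matrix(stats::rnorm(n * cfg$n_reps), n) + design$delta
        x1 <- type_transform(clip_mat(l1, spec_base), k, spec_base)
        x2 <- type_transform(clip_mat(l2, spec_base), k, spec_base)
        row$ratio_sim <- mean_smd_cols(x1, x2) / es
      }
      out[[length(out) + 1L]] <- row
    }
  }
  do.call(rbind, out)
}
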