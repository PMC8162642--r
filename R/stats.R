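#' Calibration-factor fit through the origin
#'
#' Least-squares slope of MS2 versus PP7 fluorescence constrained through the
#' origin, `alpha = sum(ms2 * pp7) / sum(pp7^2)` — the interlaced-reporter
#' estimate of the mCherry/eGFP calibration factor, where both channels
#' report the identical transcriptional signal.  Also returns the per-point
#' ratio distribution (`ms2 / pp7`) mean and sd.
#'
#' @param ms2_values,pp7_values Paired fluorescence values (>= 2 pairs; not
#'   all `pp7_values` zero).  Pairs with missing values are dropped.
#' @return A one-row tibble: `alpha`, `alpha_se` (slope standard error),
#'   `ratio_mean`, `ratio_sd`, `n`.
#' @export
fit_alpha_through_origin <- function(ms2_values, pp7_values) {
  keep <- !is.na(ms2_values) & !is.na(pp7_values)
  m <- ms2_values[keep]; p <- pp7_values[keep]
  if (length(m) < 2) stop("need at least 2 paired points")
  if (all(p == 0)) stop("all pp7 values are zero")
  alpha <- sum(m * p) / sum(p^2)
  resid <- m - alpha * p
  dof <- length(m) - 1
  se <- sqrt(sum(resid^2) / dof / sum(p^2))
  ratios <- (m / p)[p > 0]
  tibble(alpha = alpha, alpha_se = se,
         ratio_mean = mean(ratios), ratio_sd = sd(ratios),
         n = length(m))
}

#' Two-color decomposition of the squared coefficient of variation
#'
#' Splits the total squared CV of paired two-color measurements of the same
#' biological quantity into an uncorrelated part (channel differences:
#' random measurement noise) and a correlated part (covariance: biological
#' plus systematic variability).  With `m`, `p` the paired values (the
#' second channel already rescaled into the first's units):
#' \deqn{CV^2_{uncorr} = \langle(m-p)^2\rangle / (2\langle m\rangle\langle p\rangle)}
#' \deqn{CV^2_{corr} = (\langle mp\rangle - \langle m\rangle\langle p\rangle) / (\langle m\rangle\langle p\rangle)}
#' \deqn{CV^2_{total} = \langle m^2+p^2\rangle / (2\langle m\rangle\langle p\rangle) - 1}
#' The additivity `total = correlated + uncorrelated` is an algebraic
#' identity, exact on every input.  Covariance-based estimators may dip
#' slightly below 0 on finite samples.
#'
#' @param channel_a,channel_b Paired positive-mean measurements in common
#'   units.
#' @return A one-row tibble: `cv2_total`, `cv2_correlated`,
#'   `cv2_uncorrelated`, `n`.
#' @export
decompose_cv2 <- function(channel_a, channel_b) {
  keep <- !is.na(channel_a) & !is.na(channel_b)
  m <- channel_a[keep]; p <- channel_b[keep]
  mm <- mean(m); mp <- mean(p)
  if (mm <= 0 || mp <= 0) stop("channel means must be positive")
  cv2_unc <- mean((m - p)^2) / (2 * mm * mp)
  cv2_cor <- (mean(m * p) - mm * mp) / (mm * mp)
  cv2_tot <- mean(m^2 + p^2) / (2 * mm * mp) - 1
  tibble(cv2_total = cv2_tot, cv2_correlated = cv2_cor,
         cv2_uncorrelated = cv2_unc, n = length(m))
}

#' Bootstrapped coefficient of variation
#'
#' CV (sd/mean) or squared CV of a sample, with a standard error estimated as
#' the sd of the statistic across `n_boot` with-replacement resamples.
#'
#' @param values Numeric sample (n >= 2, nonzero mean).
#' @param n_boot Number of bootstrap resamples (default 100).
#' @param seed Integer seed.
#' @param squared Return CV^2 instead of CV.
#' @return A one-row tibble: `cv` (or `cv2`), `se`, `n`, `n_boot`.
#' @export
bootstrap_cv <- function(values, n_boot = 100, seed = 1L, squared = FALSE) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need n >= 2")
  if (mean(values) == 0) stop("zero mean")
  stat <- function(x) {
    cv <- sd(x) / mean(x)
    if (squared) cv^2 else cv
  }
  boots <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      stat(sample(values, length(values), replace = TRUE))
    }, numeric(1))
  })
  out <- tibble(value = stat(values), se = sd(boots),
                n = length(values), n_boot = n_boot)
  names(out)[1] <- if (squared) "cv2" else "cv"
  out
}

#' Spearman rank correlation with p-value
#'
#' Non-parametric measure of association: Pearson correlation of the average
#' ranks.  The p-value uses the exact permutation null for n <= 9 without
#' ties and the t-approximation otherwise (via [stats::cor.test()]).
#'
#' @param x,y Paired numeric vectors (n >= 3, finite, non-constant).
#' @return A one-row tibble: `rho`, `p_value`, `n`.
#' @export
spearman <- function(x, y) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need n >= 3 finite pairs")
  if (var(x) == 0 || var(y) == 0) stop("undefined ranks: constant input")
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  exact <- length(x) <= 9 && !ties
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = exact)
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Mean nascent-transcript density on the gene body
#'
#' `density = r_mean / v_elon`: at steady state, transcripts initiated at
#' rate `r_mean` and traveling at `v_elon` are spaced `v_elon / r_mean` kb
#' apart, so the gene body carries `r_mean / v_elon` transcripts (in AU) per
#' kb.
#'
#' @param r_mean Mean initiation rate (AU/min), vectorized.
#' @param v_elon Elongation rate (kb/min), > 0.
#' @return Density in AU/kb.
#' @export
transcript_density <- function(r_mean, v_elon) {
  if (any(v_elon <= 0)) stop("v_elon must be > 0")
  r_mean / v_elon
}

#' Fraction of the gene occupied by RNAP footprints
#'
#' `density * footprint / 1000` (density in molecules/kb, footprint in
#' bases).  Values above 1 are reported as full occupancy (capped at 1).
#'
#' @param density Molecule density (molecules/kb), >= 0.
#' @param footprint DNA footprint per molecule (bases), > 0; 40 for RNAP.
#' @return Occupied fraction in `[0, 1]`.
#' @export
occupancy_fraction <- function(density, footprint = 40) {
  if (any(density < 0)) stop("density must be >= 0")
  if (any(footprint <= 0)) stop("footprint must be > 0")
  pmin(density * footprint / 1000, 1)
}

#' Bin per-cell results along the anterior-posterior axis
#'
#' Groups cells into AP-position bins and reports, per bin and parameter,
#' the mean, its standard error, and the CV with a bootstrapped standard
#' error.  Default bins are 2.5% of embryo length.
#'
#' @param results Tibble with `ap_position` and the parameter columns.
#' @param bin_edges Numeric vector of bin edges in `[0, 1]`.
#' @param params Parameter columns to summarize.
#' @param n_boot,seed Bootstrap settings for the CV standard error.
#' @return A tibble with columns `bin`, `bin_mid`, `parameter`, `n`, `mean`,
#'   `sem`, `cv`, `cv_se`; empty bins are absent.
#' @export
bin_by_position <- function(results, bin_edges = seq(0, 1, by = 0.025),
                            params = c("r_mean", "v_elon", "tau_cleave",
                                       "alpha"),
                            n_boot = 100, seed = 1L) {
  if (!"ap_position" %in% names(results)) stop("results need ap_position")
  params <- intersect(params, names(results))
  results$bin <- cut(results$ap_position, bin_edges, include.lowest = TRUE)
  mids <- (head(bin_edges, -1) + tail(bin_edges, -1)) / 2
  purrr::map_dfr(params, function(p) {
    results |>
      dplyr::filter(!is.na(.data$bin), !is.na(.data[[p]])) |>
      dplyr::group_by(.data$bin) |>
      dplyr::summarise(
        parameter = p,
        n = dplyr::n(),
        mean = mean(.data[[p]]),
        sem = sd(.data[[p]]) / sqrt(dplyr::n()),
        cv = ifelse(dplyr::n() >= 2 && mean(.data[[p]]) != 0,
                    sd(.data[[p]]) / mean(.data[[p]]), NA_real_),
        cv_se = if (dplyr::n() >= 2 && mean(.data[[p]]) != 0) {
          bootstrap_cv(.data[[p]], n_boot = n_boot, seed = seed)$se
        } else NA_real_,
        .groups = "drop"
      ) |>
      dplyr::mutate(bin_mid = mids[as.integer(.data$bin)], .after = "bin")
  })
}

#' Posterior-propagation Monte Carlo for cross-cell correlations
#'
#' Point-estimate correlations ignore posterior uncertainty; this check
#' propagates it: for each of `n_draws` rounds, one post-burn-in sample
#' vector is drawn per cell, the cross-cell Spearman correlation between the
#' two parameters (or between transcript density `r_mean / v_elon` and a
#' parameter) is computed, and the distribution of draws is returned.
#'
#' @param chains List of `tx_chain` objects, one per cell, all containing
#'   both parameters.
#' @param param_a,param_b Parameter names; either may be `"density"` for
#'   `r_mean / v_elon`.
#' @param n_draws Number of Monte Carlo draws.
#' @param burn_in_fraction Burn-in fraction discarded per chain.
#' @param seed Integer seed.
#' @param ci_level Central-interval level for the summary.
#' @return A list with `draws` (tibble `draw`, `rho`), and `summary`
#'   (one-row tibble: `rho_mean`, `ci_lo`, `ci_hi`, `n_cells`, `n_draws`).
#' @export
posterior_correlation_mc <- function(chains, param_a, param_b,
                                     n_draws = 200, burn_in_fraction = 0.25,
                                     seed = 1L, ci_level = 0.95) {
  get_col <- function(mat, p) {
    if (p == "density") mat[, "r_mean"] / mat[, "v_elon"] else mat[, p]
  }
  post <- lapply(chains, function(ch) {
    n <- nrow(ch)
    kept <- (floor(burn_in_fraction * n) + 1):n
    m <- unclass(ch)[kept, , drop = FALSE]
    cbind(a = get_col(m, param_a), b = get_col(m, param_b))
  })
  rhos <- withr::with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      ab <- vapply(post, function(m) m[sample.int(nrow(m), 1), ],
                   numeric(2))
      suppressWarnings(cor(ab[1, ], ab[2, ], method = "spearman"))
    }, numeric(1))
  })
  a <- (1 - ci_level) / 2
  list(draws = tibble(draw = seq_len(n_draws), rho = rhos),
       summary = tibble(rho_mean = mean(rhos),
                        ci_lo = quantile(rhos, a, names = FALSE),
                        ci_hi = quantile(rhos, 1 - a, names = FALSE),
                        n_cells = length(chains), n_draws = n_draws))
}
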