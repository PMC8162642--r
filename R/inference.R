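#' Estimate per-channel observation noise from a trace
#'
#' Robust noise scale from the second differences of each channel: for a
#' signal that is locally linear plus iid Gaussian noise of sd `sigma`, the
#' double-differenced series has sd `sqrt(6) * sigma`, so
#' `mad(diff(x, differences = 2)) / sqrt(6)` estimates `sigma` while ignoring
#' the smooth trace shape and the occasional outlier.
#'
#' @param trace A single-cell trace tibble (see [tx_trace()]).
#' @return Named numeric vector `c(ms2 = ..., pp7 = ...)` in each channel's AU.
#' @export
estimate_noise_sd <- function(trace) {
  one <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) < 4) stop("too few points to estimate noise")
    s <- mad(diff(x, differences = 2)) / sqrt(6)
    max(s, 1e-3)
  }
  c(ms2 = one(trace$ms2_au), pp7 = one(trace$pp7_au))
}

#' Gaussian log-likelihood of a trace under the forward model
#'
#' Independent Gaussian observation model per channel: the log density is the
#' sum over non-missing time points of Gaussian log densities of the
#' residuals (observed minus [predict_traces()]), with per-channel noise sd.
#' Missing values contribute nothing.
#'
#' @param params A [transcription_params()] object.
#' @param trace A single-cell trace tibble.
#' @param geom A [reporter_geometry()] object.
#' @param noise_sd Length-2 numeric `c(ms2, pp7)`, both > 0 (AU of each
#'   channel).
#' @param refine Loading-grid refinement passed to [predict_traces()].
#' @return Log density (scalar).
#' @export
log_likelihood <- function(params, trace, geom, noise_sd, refine = 4) {
  if (any(noise_sd <= 0)) stop("noise_sd must be > 0")
  ok <- !is.na(trace$ms2_au) | !is.na(trace$pp7_au)
  if (!any(ok)) stop("no data: trace is all missing")
  pred <- predict_traces(params, geom, trace$time_min, refine)
  ll <- 0
  for (ch in c("ms2", "pp7")) {
    col <- paste0(ch, "_au")
    obs <- trace[[col]]
    keep <- !is.na(obs)
    if (!any(keep)) next
    sdv <- noise_sd[[if (ch == "ms2") 1 else 2]]
    r <- obs[keep] - pred[[col]][keep]
    ll <- ll + sum(stats::dnorm(r, mean = 0, sd = sdv, log = TRUE))
  }
  ll
}

#' Default parameter bounds for the box prior
#'
#' Bounds bracket all values reported for this system with room to spare:
#' elongation rates 0.1-10 kb/min, cleavage times 0-15 min, calibration
#' factors 0.01-1, rates and basal levels non-negative.  Data-dependent
#' bounds (onset time, basal levels, initiation rate) are derived loosely
#' from the trace when one is supplied.
#'
#' @param trace Optional single-cell trace used to scale data-dependent
#'   bounds.
#' @return Named list of length-2 numeric vectors (lower, upper).
#' @export
default_bounds <- function(trace = NULL) {
  pp7_max <- if (is.null(trace)) 100 else max(trace$pp7_au, na.rm = TRUE)
  ms2_max <- if (is.null(trace)) 100 else max(trace$ms2_au, na.rm = TRUE)
  t_max <- if (is.null(trace)) 18 else max(trace$time_min)
  list(
    r_mean = c(0, max(4 * pp7_max / 2, 10)),
    dr = c(-15, 15),
    v_elon = c(0.1, 10),
    tau_cleave = c(0, 15),
    t_on = c(0, max(t_max - 1, 1)),
    alpha = c(0.01, 1),
    ms2_basal = c(0, max(0.5 * ms2_max, 1)),
    pp7_basal = c(0, max(0.5 * pp7_max, 1))
  )
}

bounds_matrix <- function(bounds, n_knots, sample_noise = FALSE) {
  nm <- c("r_mean", paste0("dr", seq_len(n_knots)), "v_elon", "tau_cleave",
          "t_on", "alpha", "ms2_basal", "pp7_basal")
  if (sample_noise) nm <- c(nm, "sd_ms2", "sd_pp7")
  lo <- hi <- setNames(numeric(length(nm)), nm)
  for (p in nm) {
    b <- if (grepl("^dr[0-9]+$", p)) {
      bounds$dr
    } else if (p %in% c("sd_ms2", "sd_pp7")) {
      bounds$noise %||% c(1e-3, 50)
    } else {
      bounds[[p]]
    }
    if (is.null(b)) stop("no bounds for parameter ", p)
    lo[p] <- b[1]; hi[p] <- b[2]
  }
  cbind(lo = lo, hi = hi)
}

#' Log prior density
#'
#' Uniform (box) priors on every parameter — 0 inside the bounds, `-Inf`
#' outside — plus an additional zero-mean Gaussian penalty on the `dR` knots
#' (sd `dr_penalty_sd`) that keeps the initiation-rate fluctuations small
#' relative to the mean rate.  Parameter vectors violating the positivity
#' invariant `r_mean + dR >= 0` at any knot are also rejected.
#'
#' @param params A [transcription_params()] object.
#' @param bounds Named list as returned by [default_bounds()].
#' @param dr_penalty_sd Gaussian penalty sd on each `dR` knot (AU/min).
#' @return Log density (unnormalized); `-Inf` outside the support.
#' @export
log_prior <- function(params, bounds = default_bounds(), dr_penalty_sd = 1) {
  bm <- bounds_matrix(bounds, length(params$dr_knots))
  v <- params_to_vector(params)
  if (any(v < bm[, "lo"]) || any(v > bm[, "hi"])) return(-Inf)
  if (any(params$r_mean + params$dr_knots < 0)) return(-Inf)
  -0.5 * sum((params$dr_knots / dr_penalty_sd)^2)
}

#' Inference configuration
#'
#' Settings for the per-cell adaptive Metropolis sampler.  Defaults follow a
#' Haario-style scheme: proposal covariance adapted from the chain history
#' starting after `n_adapt` steps, scaled by `2.38^2 / d`.
#'
#' @param n_steps Total MCMC steps (default 30000).
#' @param n_adapt Step at which covariance adaptation begins (default 100).
#' @param burn_in Fraction of the chain discarded by [summarize_chain()]
#'   (default 0.25).
#' @param bounds Named list of box-prior bounds; NULL = [default_bounds()]
#'   derived from the trace.
#' @param init Optional named numeric vector of initial values (partial is
#'   fine); remaining entries use data-driven heuristics.
#' @param noise_sd Length-2 `c(ms2, pp7)` observation noise, treated as
#'   fixed and known when supplied.  With the default `NULL`, the per-channel
#'   noise sds are sampled as two additional parameters (`sd_ms2`, `sd_pp7`,
#'   uniform box prior, initialized from [estimate_noise_sd()]), so posterior
#'   credible intervals account for noise-scale uncertainty.
#' @param n_knots Number of evenly spaced `dR` knots over the fit window.
#' @param dr_penalty_sd Gaussian prior sd on each `dR` knot (AU/min).
#' @param refine Loading-grid refinement for the forward model.
#' @param ci_level Credible-interval level used in summaries.
#' @param seed Integer RNG seed; identical seeds give identical chains.
#' @return A list of class `tx_inference_config`.
#' @export
tc_inference_config <- function(n_steps = 30000, n_adapt = 100,
                                burn_in = 0.25, bounds = NULL, init = NULL,
                                noise_sd = NULL, n_knots = 5,
                                dr_penalty_sd = 1, refine = 4,
                                ci_level = 0.9, seed = 1L) {
  stopifnot(n_steps > 0, n_adapt >= 10, burn_in >= 0, burn_in < 1,
            n_knots >= 1)
  structure(list(n_steps = n_steps, n_adapt = n_adapt, burn_in = burn_in,
                 bounds = bounds, init = init, noise_sd = noise_sd,
                 n_knots = n_knots, dr_penalty_sd = dr_penalty_sd,
                 refine = refine, ci_level = ci_level, seed = seed),
            class = "tx_inference_config")
}

# Data-driven starting point: onset from the first sustained rise, basal
# levels from the pre-onset floor, amplitude-based guesses for r_mean and
# alpha, field-typical mid values for v_elon and tau_cleave.
initial_params <- function(trace, geom, bounds, n_knots, knot_times) {
  ms2 <- trace$ms2_au; pp7 <- trace$pp7_au; tt <- trace$time_min
  pp7_floor <- min(pp7, na.rm = TRUE)
  ms2_floor <- min(ms2, na.rm = TRUE)
  pp7_amp <- max(pp7, na.rm = TRUE) - pp7_floor
  ms2_amp <- max(ms2, na.rm = TRUE) - ms2_floor
  rise <- which(!is.na(ms2) & ms2 > ms2_floor + 0.2 * max(ms2_amp, 1e-6))
  t_on0 <- if (length(rise)) max(tt[rise[1]] - 0.5, 0.1) else 1
  v0 <- 1.7
  tau0 <- 2
  L <- geom$gene_length
  dwell_pp7 <- max(L / v0 + tau0 - mean(c(geom$pp7_start, geom$pp7_end)) / v0, 0.5)
  r0 <- max(pp7_amp / dwell_pp7, 0.5)
  alpha0 <- if (pp7_amp > 0) {
    dwell_ms2 <- L / v0 + tau0 - mean(c(geom$ms2_start, geom$ms2_end)) / v0
    min(max(ms2_amp / (r0 * dwell_ms2), 0.02), 0.9)
  } else 0.15
  clamp <- function(x, b) min(max(x, b[1] + 1e-6 * diff(b)), b[2] - 1e-6 * diff(b))
  p <- transcription_params(
    r_mean = clamp(r0, bounds$r_mean),
    dr_knots = numeric(n_knots),
    v_elon = clamp(v0, bounds$v_elon),
    tau_cleave = clamp(tau0, bounds$tau_cleave),
    t_on = clamp(t_on0, bounds$t_on),
    alpha = clamp(alpha0, bounds$alpha),
    ms2_basal = clamp(ms2_floor, bounds$ms2_basal),
    pp7_basal = clamp(pp7_floor, bounds$pp7_basal),
    knot_times = knot_times
  )
  p
}

#' Run adaptive Metropolis MCMC for one cell
#'
#' Samples the posterior of the full transcription-cycle parameter vector
#' (mean initiation rate, `dR` knots, elongation rate, cleavage time, onset
#' time, calibration factor, basal levels) for a single cell's dual-channel
#' trace, targeting [log_likelihood()] + [log_prior()].  The proposal is a
#' Gaussian random walk whose covariance is adapted from the accumulated
#' chain history (scaled empirical covariance plus a small regularizer) after
#' `n_adapt` steps.  Identical seeds give bitwise-identical chains.
#'
#' @param trace A single-cell trace tibble with at least 20 non-missing
#'   points per channel (by default).
#' @param geom A [reporter_geometry()] object.
#' @param config A [tc_inference_config()].
#' @param min_points Minimal non-missing points required per channel.
#' @return An object of class `tx_chain`: the sample matrix with attributes
#'   `log_posterior`, `acceptance_rate`, `seed`, `trace`, `geom`, `config`,
#'   `noise_sd`, `knot_times`.
#' @export
run_mcmc <- function(trace, geom, config = tc_inference_config(),
                     min_points = 20) {
  validate_trace(trace)
  if (length(unique(trace$cell_id)) != 1) stop("run_mcmc expects one cell")
  for (col in c("ms2_au", "pp7_au")) {
    if (sum(!is.na(trace[[col]])) < min_points) {
      stop("trace has fewer than ", min_points, " non-missing points in ", col)
    }
  }
  bounds <- config$bounds %||% default_bounds(trace)
  sample_noise <- is.null(config$noise_sd)
  noise_sd <- config$noise_sd %||% estimate_noise_sd(trace)
  if (sample_noise && is.null(bounds$noise)) {
    bounds$noise <- c(1e-3, 10 * max(noise_sd))
  }
  n_knots <- config$n_knots
  knot_times <- seq(min(trace$time_min), max(trace$time_min),
                    length.out = max(n_knots, 2))[seq_len(n_knots)]
  if (n_knots == 1) knot_times <- mean(range(trace$time_min))
  template <- initial_params(trace, geom, bounds, n_knots, knot_times)
  if (!is.null(config$init)) {
    v <- params_to_vector(template)
    common <- intersect(names(config$init), names(v))
    v[common] <- config$init[common]
    template <- vector_to_params(v, template)
  }
  bm <- bounds_matrix(bounds, n_knots, sample_noise)
  d <- nrow(bm)

  # precompute the loading grid and dR interpolation weights once per cell
  grid <- loading_grid(trace$time_min, config$refine)
  interp_w <- vapply(seq_len(n_knots), function(k) {
    e <- numeric(n_knots); e[k] <- 1
    p <- template; p$dr_knots <- e
    dr_interp(p, grid$mid)
  }, numeric(length(grid$mid)))

  obs_ms2 <- trace$ms2_au; obs_pp7 <- trace$pp7_au
  keep_m <- !is.na(obs_ms2); keep_p <- !is.na(obs_pp7)
  times <- trace$time_min
  log_post <- function(v) {
    p <- vector_to_params(v, template)
    if (any(v < bm[, "lo"]) || any(v > bm[, "hi"])) return(-Inf)
    if (any(p$r_mean + p$dr_knots < 0)) return(-Inf)
    sd_m <- if (sample_noise) v[[length(v) - 1]] else noise_sd[[1]]
    sd_p <- if (sample_noise) v[[length(v)]] else noise_sd[[2]]
    lp <- -0.5 * sum((p$dr_knots / config$dr_penalty_sd)^2)
    rate_mid <- p$r_mean + as.numeric(interp_w %*% p$dr_knots)
    pred <- fm_convolve(times, grid$mid, rate_mid, grid$dt, p$t_on,
                        p$v_elon, p$tau_cleave, geom$gene_length,
                        geom$ms2_start, geom$ms2_end, geom$pp7_start,
                        geom$pp7_end, p$alpha, p$ms2_basal, p$pp7_basal)
    ll <- sum(stats::dnorm(obs_ms2[keep_m] - pred$ms2[keep_m], 0,
                           sd_m, log = TRUE)) +
      sum(stats::dnorm(obs_pp7[keep_p] - pred$pp7[keep_p], 0,
                       sd_p, log = TRUE))
    lp + ll
  }

  run <- function() {
    theta <- params_to_vector(template)
    if (sample_noise) {
      theta <- c(theta, sd_ms2 = unname(noise_sd[[1]]),
                 sd_pp7 = unname(noise_sd[[2]]))
    }
    lp <- log_post(theta)
    if (!is.finite(lp)) {
      # retry from jittered positions inside the box
      for (k in 1:50) {
        theta_try <- bm[, "lo"] + runif(d) * (bm[, "hi"] - bm[, "lo"])
        lp <- log_post(theta_try)
        if (is.finite(lp)) { theta <- theta_try; break }
      }
      if (!is.finite(lp)) stop("cannot initialize: log posterior not finite")
    }
    n <- config$n_steps
    samples <- matrix(NA_real_, n, d, dimnames = list(NULL, rownames(bm)))
    lps <- numeric(n)
    rng <- bm[, "hi"] - bm[, "lo"]
    scale0 <- 0.02 * rng
    sd_opt <- 2.38^2 / d
    eps <- 1e-10

    # Laplace warm start: box-constrained MAP from several starting points
    # (the posterior can be multimodal, e.g. for cells with a weak MS2
    # amplitude), keeping the best mode; its inverse Hessian scales the
    # initial proposal so the chain starts in the posterior bulk.
    neg <- function(v) {
      val <- log_post(v)
      if (is.finite(val)) -val else 1e10
    }
    C <- diag(scale0^2, d)
    starts <- list(theta)
    for (s in 1:2) {
      jit <- theta + rnorm(d, 0, 0.1 * rng)
      starts[[s + 1]] <- pmin(pmax(jit, bm[, "lo"] + 1e-6 * rng),
                              bm[, "hi"] - 1e-6 * rng)
    }
    best <- NULL
    for (st in starts) {
      opt <- tryCatch(
        stats::optim(st, neg, method = "L-BFGS-B",
                     lower = bm[, "lo"] + 1e-8 * rng,
                     upper = bm[, "hi"] - 1e-8 * rng,
                     control = list(maxit = 200), hessian = FALSE),
        error = function(e) NULL
      )
      if (!is.null(opt) && opt$value < 1e9 &&
          (is.null(best) || opt$value < best$value)) {
        best <- opt
      }
    }
    if (!is.null(best)) {
      theta <- best$par
      lp <- log_post(theta)
      H <- tryCatch(stats::optimHess(theta, neg), error = function(e) NULL)
      Ci <- if (!is.null(H)) tryCatch(solve(H), error = function(e) NULL)
      if (!is.null(Ci)) {
        Ci <- (Ci + t(Ci)) / 2
        ev <- eigen(Ci, symmetric = TRUE, only.values = TRUE)$values
        if (all(ev > 0)) C <- Ci
      }
    }
    chol_C <- tryCatch(chol(C), error = function(e) diag(scale0))
    mu <- theta
    log_lam <- 0          # global proposal scale, tuned to ~23% acceptance
    accepted <- 0L
    Ch <- diag(0, d)
    for (i in seq_len(n)) {
      # small fixed fraction of wide proposals lets the chain hop between
      # modes (e.g. the slow/fast elongation modes of weak-MS2 cells)
      wide <- if (runif(1) < 0.05) 5 else 1
      prop <- theta + wide * exp(log_lam / 2) * as.numeric(rnorm(d) %*% chol_C)
      lp_prop <- log_post(prop)
      a_prob <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
      if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp) {
        theta <- prop; lp <- lp_prop; accepted <- accepted + 1L
      }
      samples[i, ] <- theta
      lps[i] <- lp
      # Robbins-Monro step on the global scale (target acceptance 0.234)
      log_lam <- log_lam + min(1, 5 / i^0.6) * (a_prob - 0.234)
      # online mean/covariance of the history (Haario adaptation)
      dlt <- theta - mu
      mu <- mu + dlt / i
      if (i > 1) Ch <- Ch + tcrossprod(dlt) * (i - 1) / i
      if (i >= config$n_adapt && i %% 25 == 0) {
        C <- sd_opt * (Ch / (i - 1) + eps * diag(d))
        ch <- tryCatch(chol(C), error = function(e) NULL)
        if (!is.null(ch)) chol_C <- ch
      }
    }
    list(samples = samples, lps = lps, acc = accepted / n)
  }
  res <- if (!is.null(config$seed)) withr::with_seed(config$seed, run()) else run()

  structure(res$samples,
            log_posterior = res$lps,
            acceptance_rate = res$acc,
            seed = config$seed,
            trace = trace, geom = geom, config = config,
            noise_sd = noise_sd, knot_times = knot_times,
            template = template,
            class = c("tx_chain", "matrix", "array"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.tx_chain <- function(x, ...) {
  cat(sprintf("<tx_chain> %d steps x %d parameters, acceptance rate %.2f\n",
              nrow(x), ncol(x), attr(x, "acceptance_rate")))
  invisible(x)
}

#' Summarize a posterior chain
#'
#' Discards the first `burn_in_fraction` of the chain, then reports the
#' posterior mean (the point estimate retained for downstream analysis),
#' posterior sd, and a central credible interval per parameter.  The fit
#' quality of the posterior-mean prediction and a bursting flag are attached
#' when the chain carries its trace.
#'
#' @param chain A `tx_chain` from [run_mcmc()].
#' @param burn_in_fraction Fraction in `[0, 1)` discarded from the front.
#' @param ci_level Central credible-interval level.
#' @return An object of class `tx_fit`: a tibble with columns `parameter`,
#'   `mean`, `sd`, `ci_lo`, `ci_hi`, plus attributes `fit_quality`,
#'   `bursting`, `burn_in`, `params` (posterior-mean [transcription_params()]).
#' @export
summarize_chain <- function(chain, burn_in_fraction = 0.25, ci_level = 0.9) {
  if (burn_in_fraction < 0 || burn_in_fraction >= 1) {
    stop("burn_in_fraction must be in [0, 1)")
  }
  n <- nrow(chain)
  drop_n <- as.integer(floor(burn_in_fraction * n))
  if (n - drop_n < 1) stop("empty post-burn-in chain")
  kept <- chain[(drop_n + 1):n, , drop = FALSE]
  a <- (1 - ci_level) / 2
  out <- tibble(
    parameter = colnames(kept),
    mean = unname(apply(kept, 2, mean)),
    sd = unname(apply(kept, 2, sd)),
    ci_lo = unname(apply(kept, 2, quantile, probs = a, names = FALSE)),
    ci_hi = unname(apply(kept, 2, quantile, probs = 1 - a, names = FALSE))
  )
  fq <- NA_real_; burst <- NA; p_hat <- NULL
  trace <- attr(chain, "trace"); geom <- attr(chain, "geom")
  if (!is.null(trace) && !is.null(geom)) {
    p_hat <- vector_to_params(setNames(out$mean, out$parameter),
                              attr(chain, "template"))
    cfg <- attr(chain, "config")
    pred <- predict_traces(p_hat, geom, trace$time_min,
                           refine = cfg$refine %||% 4)
    fq <- fit_quality(trace, pred, alpha = p_hat$alpha)
    burst <- tryCatch(detect_bursting(trace, pred, p_hat),
                      error = function(e) NA)
  }
  structure(out, class = c("tx_fit", class(out)),
            fit_quality = fq, bursting = burst,
            burn_in = drop_n, n_kept = n - drop_n,
            params = p_hat, trace = trace, geom = geom)
}

#' @export
print.tx_fit <- function(x, ...) {
  cat(sprintf("<tx_fit> fit quality %.3f, bursting: %s, %d samples kept\n",
              attr(x, "fit_quality"), attr(x, "bursting"), attr(x, "n_kept")))
  NextMethod()
}

#' Chain autocorrelation function
#'
#' Normalized autocorrelation of each parameter's raw chain as a function of
#' lag; rapid decay indicates good mixing.
#'
#' @param chain A `tx_chain` (or numeric matrix with named columns).
#' @param max_lag Maximum lag (must be < chain length).
#' @return A tibble with columns `parameter`, `lag`, `acf`; `acf` is 1 at
#'   lag 0.
#' @export
chain_autocorrelation <- function(chain, max_lag = 100) {
  if (nrow(chain) <= max_lag) stop("chain length must exceed max_lag")
  m <- unclass(chain)[, , drop = FALSE]
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  purrr::map_dfr(colnames(m), function(p) {
    x <- m[, p]
    if (var(x) == 0) stop("degenerate chain: zero variance in ", p)
    a <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)
    tibble(parameter = p, lag = 0:max_lag, acf = as.numeric(a$acf))
  })
}

#' Infer transcription-cycle parameters for every cell of a trace table
#'
#' Runs [run_mcmc()] and [summarize_chain()] independently per cell and
#' collects posterior means, sds, fit quality and the bursting flag into one
#' tibble (one row per cell).  Per-cell seeds are derived deterministically
#' from `config$seed`.
#'
#' @param traces A trace table covering one or more cells.
#' @param geom A [reporter_geometry()] object.
#' @param config A [tc_inference_config()].
#' @param keep_chains Keep the full `tx_chain` objects in a list column
#'   (needed for posterior-propagation statistics).
#' @return A tibble with columns `cell_id`, `embryo_id`, `ap_position`,
#'   posterior means (`r_mean`, `v_elon`, `tau_cleave`, `t_on`, `alpha`,
#'   `ms2_basal`, `pp7_basal`), posterior sds (`*_sd`), `fit_quality`,
#'   `bursting`, and optionally `chain`/`fit` list columns.
#' @export
infer_cells <- function(traces, geom, config = tc_inference_config(),
                        keep_chains = TRUE) {
  cells <- split_cells(traces)
  base_seed <- config$seed %||% 1L
  rows <- purrr::imap(cells, function(tr, id) {
    cfg <- config
    cfg$seed <- (base_seed + 7919L * match(id, names(cells))) %% 2147483647L
    chain <- run_mcmc(tr, geom, cfg)
    fit <- summarize_chain(chain, burn_in_fraction = config$burn_in,
                           ci_level = config$ci_level)
    means <- setNames(fit$mean, fit$parameter)
    sds <- setNames(fit$sd, paste0(fit$parameter, "_sd"))
    keep <- c("r_mean", "v_elon", "tau_cleave", "t_on", "alpha",
              "ms2_basal", "pp7_basal")
    out <- tibble(cell_id = id,
                  embryo_id = tr$embryo_id[1],
                  ap_position = tr$ap_position[1],
                  !!!as.list(means[keep]),
                  !!!as.list(sds[paste0(keep, "_sd")]),
                  fit_quality = attr(fit, "fit_quality"),
                  bursting = isTRUE(attr(fit, "bursting")))
    if (keep_chains) {
      out$chain <- list(chain)
      out$fit <- list(fit)
    }
    out
  })
  dplyr::bind_rows(rows)
}

#' @rdname tidy-tx
#' @param x A `tx_chain` or `tx_fit` object.
#' @param ... Unused.
#' @export
tidy.tx_chain <- function(x, ...) {
  s <- summarize_chain(x, burn_in_fraction = 0)
  tibble::as_tibble(s)
}

#' Tidy and glance methods for inference objects
#'
#' `tidy()` returns one row per parameter (posterior mean, sd, credible
#' interval); `glance()` returns a one-row model-level summary.
#'
#' @name tidy-tx
#' @export
tidy.tx_fit <- function(x, ...) tibble::as_tibble(x)

#' @rdname tidy-tx
#' @export
glance.tx_chain <- function(x, ...) {
  tibble(n_steps = nrow(x), n_params = ncol(x),
         acceptance_rate = attr(x, "acceptance_rate"),
         max_log_posterior = max(attr(x, "log_posterior")),
         seed = attr(x, "seed") %||% NA_integer_)
}

#' @rdname tidy-tx
#' @export
glance.tx_fit <- function(x, ...) {
  tibble(fit_quality = attr(x, "fit_quality"),
         bursting = attr(x, "bursting"),
         burn_in = attr(x, "burn_in"), n_kept = attr(x, "n_kept"))
}
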