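#' Generate one synthetic trace from known parameters
#'
#' Forward-model prediction plus independent zero-mean Gaussian measurement
#' noise per channel, clipped at 0 (fluorescence cannot be negative).  The
#' generating parameters are attached as attribute `truth`.
#'
#' @param true_params A [transcription_params()] object.
#' @param geom A [reporter_geometry()] object.
#' @param noise_sd Length-2 `c(ms2, pp7)` noise sd in each channel's AU.
#' @param times Observation times (min); default 15-s sampling over 18 min.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param cell_id,embryo_id,ap_position Trace metadata.
#' @return A trace tibble (see [tx_trace()]) with attribute `truth`.
#' @export
generate_trace <- function(true_params, geom, noise_sd = c(0.5, 2),
                           times = seq(0, 18, by = 0.25), seed = 1L,
                           cell_id = "cell_1", embryo_id = "embryo_1",
                           ap_position = 0.3) {
  pred <- predict_traces(true_params, geom, times)
  noisy <- withr::with_seed(seed, {
    list(ms2 = pmax(pred$ms2_au + rnorm(length(times), 0, noise_sd[[1]]), 0),
         pp7 = pmax(pred$pp7_au + rnorm(length(times), 0, noise_sd[[2]]), 0))
  })
  tr <- tx_trace(times, noisy$ms2, noisy$pp7, cell_id = cell_id,
                 embryo_id = embryo_id, ap_position = ap_position)
  attr(tr, "truth") <- true_params
  tr
}

#' Population specification for the synthetic-trace generator
#'
#' Defines the study conditions emulated by [generate_population()]: per-cell
#' transcription parameters drawn independently from truncated normal (or
#' log-normal) distributions, traces sampled every 15 s over an 18-min
#' nuclear-cycle window, additive Gaussian measurement noise per channel, and
#' optionally a step-like anterior-posterior profile of the mean initiation
#' rate and a small fraction of telegraph (bursting) cells.
#'
#' Default distribution centers follow the system under study: elongation
#' rate 1.72 kb/min, cleavage time 2.25 min (middle of the reported 1.5-3 min
#' range), calibration factor 0.145; the initiation-rate center (15 AU/min,
#' ~30% CV) and the generative sds are realistic single-embryo values chosen
#' once (see the methods vignette).
#'
#' @param n_cells Number of cells.
#' @param r_mean,v_elon,tau_cleave,t_on,alpha,ms2_basal,pp7_basal Length-2
#'   numeric `c(mean, sd)` generative distributions.
#' @param family `"normal"` (truncated) or `"lognormal"` (matched moments).
#' @param noise_sd Length-2 `c(ms2, pp7)` measurement noise.
#' @param dt Sampling interval (min).  @param duration Trace duration (min).
#' @param ap_profile `"constant"` or `"step"`: with `"step"`, cells posterior
#'   of `step_position` have their mean initiation rate divided by
#'   `fold_change`.
#' @param step_position AP position of the expression step (embryo fraction).
#' @param fold_change Anterior/posterior fold change of the step profile.
#' @param burst_fraction Fraction of cells replaced by telegraph (ON/OFF)
#'   initiation for curation testing.
#' @param burst_on,burst_off Length-2 uniform ranges (min) for telegraph ON
#'   and OFF dwell times.
#' @param n_embryos Cells are split evenly across this many embryo ids.
#' @param seed Integer seed.
#' @return A list of class `tx_population_spec`.
#' @export
tc_population_spec <- function(n_cells = 30,
                               r_mean = c(15, 4.5),
                               v_elon = c(1.72, 0.35),
                               tau_cleave = c(2.25, 0.5),
                               t_on = c(2, 0.5),
                               alpha = c(0.145, 0.03),
                               ms2_basal = c(1, 0.3),
                               pp7_basal = c(2, 0.6),
                               family = c("normal", "lognormal"),
                               noise_sd = c(0.5, 2),
                               dt = 0.25, duration = 18,
                               ap_profile = c("constant", "step"),
                               step_position = 0.45, fold_change = 26,
                               burst_fraction = 0,
                               burst_on = c(2, 4), burst_off = c(4, 6),
                               n_embryos = 1, seed = 1L) {
  stopifnot(n_cells >= 1, burst_fraction >= 0, burst_fraction <= 1,
            all(noise_sd >= 0))
  spec <- list(n_cells = n_cells, r_mean = r_mean, v_elon = v_elon,
               tau_cleave = tau_cleave, t_on = t_on, alpha = alpha,
               ms2_basal = ms2_basal, pp7_basal = pp7_basal,
               family = match.arg(family), noise_sd = noise_sd, dt = dt,
               duration = duration, ap_profile = match.arg(ap_profile),
               step_position = step_position, fold_change = fold_change,
               burst_fraction = burst_fraction, burst_on = burst_on,
               burst_off = burst_off, n_embryos = n_embryos, seed = seed)
  if (any(vapply(spec[c("r_mean", "v_elon", "tau_cleave", "t_on", "alpha",
                        "ms2_basal", "pp7_basal")],
                 function(x) x[2] < 0, logical(1)))) {
    stop("generative sds must be >= 0")
  }
  structure(spec, class = "tx_population_spec")
}

# Draw from the configured family, truncated to [lo, hi].
draw_trunc <- function(n, ms, lo, hi, family) {
  mu <- ms[1]; s <- ms[2]
  if (s == 0) return(rep(mu, n))
  out <- numeric(n)
  for (i in seq_len(n)) {
    for (k in 1:1000) {
      x <- if (family == "lognormal") {
        sl2 <- log(1 + (s / mu)^2)
        stats::rlnorm(1, log(mu) - sl2 / 2, sqrt(sl2))
      } else {
        rnorm(1, mu, s)
      }
      if (x >= lo && x <= hi) { out[i] <- x; break }
      if (k == 1000) stop("truncated draw failed; check distribution bounds")
    }
  }
  out
}

# Telegraph state (1 = ON, 0 = OFF) on time points `t`, starting ON at t_on,
# with uniform dwell times in the configured ranges.
telegraph_state <- function(t, t_on, duration, on_range, off_range) {
  switches <- t_on
  state0 <- 1
  now <- t_on
  while (now < duration) {
    on_d <- runif(1, on_range[1], on_range[2])
    off_d <- runif(1, off_range[1], off_range[2])
    switches <- c(switches, now + on_d, now + on_d + off_d)
    now <- now + on_d + off_d
  }
  idx <- findInterval(t, switches)
  st <- ifelse(idx <= 0, 0, 1 - (idx + 1) %% 2)
  as.numeric(st)
}

#' Generate a synthetic cell population
#'
#' Draws independent true parameters per cell from the generative
#' distributions in `spec` (truncated to the model's physical ranges),
#' assigns uniform AP positions (applying the step expression profile to the
#' mean initiation rate if configured), simulates each trace through the
#' forward model with measurement noise, and optionally replaces a fraction
#' of cells with telegraph ON/OFF initiation for curation testing.
#'
#' @param spec A [tc_population_spec()].
#' @return A list with elements `traces` (one long trace tibble) and `truth`
#'   (per-cell tibble of generating parameters, including `burst_mode`).
#' @export
generate_population <- function(spec) {
  stopifnot(inherits(spec, "tx_population_spec"))
  n <- spec$n_cells
  withr::with_seed(spec$seed, {
    ap <- runif(n)
    r_mean <- draw_trunc(n, spec$r_mean, 0.5, Inf, spec$family)
    if (spec$ap_profile == "step") {
      r_mean <- ifelse(ap < spec$step_position, r_mean,
                       r_mean / spec$fold_change)
    }
    v <- draw_trunc(n, spec$v_elon, 0.3, 10, spec$family)
    tau <- draw_trunc(n, spec$tau_cleave, 0.05, 15, spec$family)
    t_on <- draw_trunc(n, spec$t_on, 0.25, spec$duration / 2, spec$family)
    alpha <- draw_trunc(n, spec$alpha, 0.02, 0.95, spec$family)
    ms2_b <- draw_trunc(n, spec$ms2_basal, 0, Inf, spec$family)
    pp7_b <- draw_trunc(n, spec$pp7_basal, 0, Inf, spec$family)
    burst <- runif(n) < spec$burst_fraction
    embryo <- paste0("embryo_", 1 + (seq_len(n) - 1) %% spec$n_embryos)
    times <- seq(0, spec$duration, by = spec$dt)
    geom <- reporter_geometry()
    cell_seeds <- sample.int(2147483646L, n)

    traces <- vector("list", n)
    for (i in seq_len(n)) {
      p <- transcription_params(
        r_mean = r_mean[i], dr_knots = numeric(5), v_elon = v[i],
        tau_cleave = tau[i], t_on = t_on[i], alpha = alpha[i],
        ms2_basal = ms2_b[i], pp7_basal = pp7_b[i],
        knot_window = c(0, spec$duration)
      )
      id <- sprintf("cell_%03d", i)
      if (burst[i]) {
        grid <- loading_grid(times, 4)
        state <- telegraph_state(grid$mid, p$t_on, spec$duration,
                                 spec$burst_on, spec$burst_off)
        pred <- convolve_rate(times, grid, p$r_mean * state, p, geom)
        sd1 <- spec$noise_sd[[1]]; sd2 <- spec$noise_sd[[2]]
        tr <- tx_trace(times,
                       pmax(pred$ms2_au + rnorm(length(times), 0, sd1), 0),
                       pmax(pred$pp7_au + rnorm(length(times), 0, sd2), 0),
                       cell_id = id, embryo_id = embryo[i], ap_position = ap[i])
      } else {
        tr <- generate_trace(p, geom, spec$noise_sd, times,
                             seed = cell_seeds[i], cell_id = id,
                             embryo_id = embryo[i], ap_position = ap[i])
      }
      traces[[i]] <- tr
    }
    truth <- tibble(cell_id = sprintf("cell_%03d", seq_len(n)),
                    embryo_id = embryo, ap_position = ap,
                    r_mean = r_mean, v_elon = v, tau_cleave = tau,
                    t_on = t_on, alpha = alpha, ms2_basal = ms2_b,
                    pp7_basal = pp7_b, burst_mode = burst)
    all_traces <- dplyr::bind_rows(traces)
    attr(all_traces, "truth") <- NULL   # per-cell truth lives in the table
    list(traces = all_traces, truth = truth)
  })
}

#' Configuration for the single-molecule stepping simulation
#'
#' Settings for the stochastic exclusion-process simulation of RNAP traffic:
#' molecules occupy a `footprint` of 40 bases, step forward one base at a
#' time at their own exponential rate, cannot overlap or pass each other, and
#' load at the promoter at the attempt rate `init_rate` whenever the first
#' footprint of the gene is clear.  Per-molecule stepping rates are drawn
#' from a Gamma distribution with mean `mean_rate` and coefficient of
#' variation `rate_cv` (`rate_cv = 0`: all molecules identical).
#'
#' @param mean_rate Mean stepping rate expressed as kb/min of net transit.
#' @param rate_cv Per-molecule rate CV (>= 0).
#' @param init_rate Initiation attempt rate (1/min).
#' @param footprint RNAP DNA footprint (bases).
#' @param tau_cleave Deterministic cleavage wait (min): a finished
#'   transcript keeps its full two-channel signal this long after its
#'   polymerase steps off the gene end, then vanishes instantly.
#' @param duration Simulated time (min).  @param dt Fluorescence sampling
#'   interval (min).
#' @param alpha Calibration factor applied to the MS2 channel of the
#'   simulated trace.
#' @param seed Integer seed.
#' @return A list of class `tx_molecule_config`.
#' @export
tc_molecule_config <- function(mean_rate = 1.72, rate_cv = 0,
                               init_rate = 10, footprint = 40,
                               tau_cleave = 2, duration = 18, dt = 0.25,
                               alpha = 0.145, seed = 1L) {
  stopifnot(mean_rate > 0, rate_cv >= 0, init_rate >= 0, footprint >= 1,
            tau_cleave >= 0)
  structure(list(mean_rate = mean_rate, rate_cv = rate_cv,
                 init_rate = init_rate, footprint = footprint,
                 tau_cleave = tau_cleave, duration = duration, dt = dt,
                 alpha = alpha, seed = seed),
            class = "tx_molecule_config")
}

#' Stochastic single-molecule stepping simulation of RNAP traffic
#'
#' Exact continuous-time (Gillespie) simulation of RNAP molecules stepping
#' base-by-base along the reporter gene with hard-core footprint exclusion
#' (see [tc_molecule_config()]).  Fluorescence is computed from the molecule
#' positions through the cassette ramps ([loop_fraction()]) and the
#' calibration factor; a molecule's signal is removed the instant it steps
#' off the gene end.
#'
#' @param config A [tc_molecule_config()].
#' @param geom A [reporter_geometry()]; the lattice length is
#'   `gene_length * 1000` bases and the cassette ramps use the geometry's kb
#'   coordinates.
#' @param cell_id,embryo_id,ap_position Metadata for the returned trace.
#' @return A list with elements `trace` (trace tibble), `molecules`
#'   (per-molecule tibble: `load_time`, `exit_time`, `step_rate` and realized
#'   `mean_velocity` in kb/min, `exited`), `trajectories` (tibble of sampled
#'   positions in bases), and `min_gap` (smallest inter-RNAP gap observed, in
#'   bases; always >= footprint).
#' @export
simulate_single_molecule <- function(config, geom = reporter_geometry(),
                                     cell_id = "cell_1",
                                     embryo_id = "embryo_1",
                                     ap_position = 0.3) {
  stopifnot(inherits(config, "tx_molecule_config"))
  lattice <- as.integer(round(geom$gene_length * 1000))
  if (config$footprint > lattice) stop("footprint exceeds lattice length")
  sample_times <- seq(0, config$duration, by = config$dt)
  res <- withr::with_seed(config$seed, {
    tasep_gillespie(lattice, as.integer(config$footprint),
                    config$init_rate, config$mean_rate * 1000,
                    config$rate_cv, config$duration, config$tau_cleave,
                    sample_times,
                    geom$ms2_start * 1000, geom$ms2_end * 1000,
                    geom$pp7_start * 1000, geom$pp7_end * 1000,
                    config$alpha)
  })
  trace <- tx_trace(sample_times, res$ms2, res$pp7, cell_id = cell_id,
                    embryo_id = embryo_id, ap_position = ap_position)
  molecules <- tibble(
    molecule = seq_along(res$load_time),
    load_time = res$load_time, exit_time = res$exit_time,
    step_rate = res$step_rate / 1000,          # kb/min
    mean_velocity = res$velocity / 1000,       # kb/min, realized over transit
    exited = res$exited == 1
  )
  trajectories <- tibble(time_min = res$traj_time, molecule = res$traj_id,
                         position_bases = res$traj_pos)
  list(trace = trace, molecules = molecules, trajectories = trajectories,
       min_gap = res$min_gap)
}

#' Cross-cell elongation-rate distribution from stepping simulations
#'
#' For each simulated cell, runs the single-molecule stepping simulation,
#' feeds the resulting two-channel trace through the MCMC inference, and
#' records the posterior-mean elongation rate — so the returned cross-cell
#' distribution includes inferential noise, and can be compared between the
#' identical-molecule (`rate_cv = 0`) and variable-molecule (`rate_cv > 0`)
#' scenarios.
#'
#' @param config A [tc_molecule_config()]; its seed is re-derived per cell.
#' @param inference_config A [tc_inference_config()].
#' @param n_cells Number of simulated cells.
#' @param geom A [reporter_geometry()].
#' @return A tibble with one row per cell: `cell_id`, `v_elon` (posterior
#'   mean), `v_elon_sd`, `n_molecules`, `mean_molecule_velocity`.
#' @export
elongation_distribution_experiment <- function(config, inference_config,
                                               n_cells = 10,
                                               geom = reporter_geometry()) {
  purrr::map_dfr(seq_len(n_cells), function(i) {
    cfg <- config
    cfg$seed <- (config$seed + 104729L * i) %% 2147483647L
    sim <- simulate_single_molecule(cfg, geom,
                                    cell_id = sprintf("sim_%03d", i))
    icfg <- inference_config
    icfg$seed <- (inference_config$seed + 7L * i) %% 2147483647L
    chain <- run_mcmc(sim$trace, geom, icfg)
    fit <- summarize_chain(chain, inference_config$burn_in)
    tibble(cell_id = sprintf("sim_%03d", i),
           v_elon = fit$mean[fit$parameter == "v_elon"],
           v_elon_sd = fit$sd[fit$parameter == "v_elon"],
           n_molecules = nrow(sim$molecules),
           mean_molecule_velocity = mean(sim$molecules$mean_velocity,
                                         na.rm = TRUE))
  })
}
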