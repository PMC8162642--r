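#' Fraction of a stem-loop cassette transcribed at a given RNAP position
#'
#' The fluorescence contributed by one nascent transcript in a channel is
#' proportional to the number of that channel's stem loops already
#' transcribed.  With loops assumed evenly spaced along the cassette, this is
#' a linear ramp: 0 before the cassette start, 1 at or past the cassette end.
#' A zero-length cassette (`cassette_start == cassette_end`) is treated as a
#' point-like step.
#'
#' @param x RNAP head position in kb from the promoter (vectorized).
#' @param cassette_start,cassette_end Cassette limits in kb,
#'   `cassette_start <= cassette_end`.
#' @return Fraction in `[0, 1]`, same length as `x`.
#' @examples
#' loop_fraction(c(0, 1, 2), 0.5, 1.5)
#' @export
loop_fraction <- function(x, cassette_start, cassette_end) {
  if (cassette_start > cassette_end) stop("cassette_start must be <= cassette_end")
  if (cassette_end > cassette_start) {
    pmin(pmax((x - cassette_start) / (cassette_end - cassette_start), 0), 1)
  } else {
    as.numeric(x >= cassette_start)
  }
}

#' Per-transcript signal as a function of transcript age
#'
#' A transcript loaded `age` minutes ago has its polymerase at position
#' `v_elon * age` (saturating at the gene end, where it waits for cleavage
#' while contributing its full cassette signal).  Once
#' `age >= L / v_elon + tau_cleave` the transcript has been cleaved and the
#' signal drops instantly to exactly 0 in both channels.
#'
#' @param age Minutes since loading (vectorized), >= 0.
#' @param params A [transcription_params()] object.
#' @param geom A [reporter_geometry()] object.
#' @param channel `"MS2"` or `"PP7"`.
#' @return Dimensionless signal in `[0, 1]` (units of one fully transcribed
#'   cassette of that channel).
#' @examples
#' g <- reporter_geometry(gene_length = 5, ms2_start = 0, ms2_end = 0,
#'                        pp7_start = 3, pp7_end = 3.5)
#' p <- transcription_params(r_mean = 10, v_elon = 2, tau_cleave = 1.5)
#' transcript_signal(1.625, p, g, "PP7")  # 0.5: head at 3.25 kb
#' @export
transcript_signal <- function(age, params, geom, channel = c("MS2", "PP7")) {
  channel <- match.arg(channel)
  if (any(age < 0)) stop("age must be >= 0")
  x <- pmin(params$v_elon * age, geom$gene_length)
  s <- if (channel == "MS2") {
    loop_fraction(x, geom$ms2_start, geom$ms2_end)
  } else {
    loop_fraction(x, geom$pp7_start, geom$pp7_end)
  }
  t_end <- geom$gene_length / params$v_elon + params$tau_cleave
  s[age >= t_end] <- 0
  s
}

# Fine loading-time grid shared by predict_traces() and the likelihood.
# Midpoint rule on a grid `refine` times finer than the observation spacing,
# spanning [min(0, times), max(times)].
loading_grid <- function(times, refine = 4) {
  if (length(times) == 0) stop("empty time grid")
  dt_obs <- if (length(times) >= 2) median(diff(times)) else 0.25
  dt <- dt_obs / refine
  lo <- min(0, times[1])
  hi <- max(times)
  m <- max(1L, ceiling((hi - lo) / dt))
  edges <- lo + (0:m) * dt
  list(mid = edges[-1] - dt / 2, hi = edges[-1], dt = dt)
}

# delta-R(t) evaluated at arbitrary times: linear interpolation between knots,
# identically 0 outside the knot range.
dr_interp <- function(params, t) {
  if (length(params$dr_knots) == 1L) {
    out <- rep(0, length(t))
    span <- range(params$knot_times)
    inside <- t >= span[1] & t <= span[2]
    out[inside] <- params$dr_knots
    return(out)
  }
  approx(params$knot_times, params$dr_knots, xout = t,
         yleft = 0, yright = 0)$y
}

# Shared convolution core: `rate_mid` is R(t') on the fine grid mid-points;
# the kernel clips each interval to the live loading window exactly.
convolve_rate <- function(times, grid, rate_mid, params, geom) {
  out <- fm_convolve(times, grid$mid, rate_mid, grid$dt, params$t_on,
                     params$v_elon, params$tau_cleave, geom$gene_length,
                     geom$ms2_start, geom$ms2_end, geom$pp7_start,
                     geom$pp7_end, params$alpha, params$ms2_basal,
                     params$pp7_basal)
  tibble(time_min = times, ms2_au = out$ms2, pp7_au = out$pp7)
}

#' Predict MS2 and PP7 fluorescence traces from transcription-cycle parameters
#'
#' Deterministic forward model: the predicted PP7 signal at time `t` is the
#' basal level plus the sum over loading times `t' in [t_on, t]` of
#' `R(t') dt'` times the per-transcript signal at age `t - t'`
#' ([transcript_signal()]); the MS2 signal is the analogous sum scaled by the
#' calibration factor `alpha`.  `R(t') = r_mean + dR(t')` with `dR` linearly
#' interpolated between its knots.  The loading-time integral is evaluated by
#' a midpoint sum on a grid `refine` times finer than the observation grid,
#' with the onset boundary handled exactly.
#'
#' @param params A [transcription_params()] object.
#' @param geom A [reporter_geometry()] object.
#' @param times Observation times (min), increasing.
#' @param refine Loading-grid refinement factor (>= 4 recommended).
#' @return A tibble with columns `time_min`, `ms2_au`, `pp7_au`.
#' @examples
#' g <- reporter_geometry()
#' p <- transcription_params(r_mean = 15, v_elon = 1.7, tau_cleave = 2, t_on = 1)
#' predict_traces(p, g, seq(0, 18, by = 0.25))
#' @export
predict_traces <- function(params, geom, times, refine = 4) {
  validate_params(params)
  if (length(times) == 0) stop("empty time grid")
  if (any(!is.finite(times))) stop("times must be finite")
  if (any(diff(times) <= 0)) stop("times must be increasing")
  grid <- loading_grid(times, refine)
  rate_mid <- params$r_mean + dr_interp(params, grid$mid)
  convolve_rate(times, grid, rate_mid, params, geom)
}

# Integral S(u) = int_0^u s(a) da of the per-transcript cassette ramp over
# age, in closed form (piecewise quadratic; saturates when the transcript is
# cleaved at age t_end).
ramp_age_integral <- function(u, a_kb, b_kb, v, t_end) {
  ua <- a_kb / v
  ub <- b_kb / v
  S_at <- function(x) {
    # antiderivative valid for x in [0, t_end], ignoring cleavage
    if (ub > ua) {
      ifelse(x <= ua, 0,
             ifelse(x <= ub, 0.5 * (x - ua)^2 / (ub - ua),
                    0.5 * (ub - ua) + (x - ub)))
    } else {
      pmax(x - ua, 0)
    }
  }
  S_at(pmin(pmax(u, 0), t_end))
}

#' Closed-form traces for a constant-rate initiation pulse
#'
#' Exact evaluation of the forward model for a pulse of constant magnitude
#' `r_mean` between `t_on` and `t_off` (the `dr_knots` fluctuations are
#' ignored).  This is the classic rise-plateau-fall "trapezoid" profile: the
#' MS2 signal rises first, the PP7 signal follows after the transit time to
#' the PP7 cassette, both plateau once the oldest transcripts start cleaving
#' at `t_on + L/v_elon + tau_cleave`, and after shut-off the 5' MS2 signal
#' falls before the 3' PP7 signal.  Used as the analytic oracle for
#' [predict_traces()].
#'
#' @inheritParams predict_traces
#' @param t_off End of the initiation pulse (min), > `t_on`; default `Inf`
#'   (no shut-off within the observation window).
#' @return A tibble with columns `time_min`, `ms2_au`, `pp7_au`.
#' @export
trapezoid_closed_form <- function(params, geom, times, t_off = Inf) {
  validate_params(params)
  if (any(diff(times) <= 0)) stop("times must be increasing")
  if (t_off <= params$t_on) stop("t_off must be > t_on")
  v <- params$v_elon
  t_end <- geom$gene_length / v + params$tau_cleave
  S <- function(u, a, b) ramp_age_integral(u, a, b, v, t_end)
  load_hi <- pmax(times - params$t_on, 0)
  load_lo <- pmax(times - t_off, 0)
  ms2 <- params$ms2_basal + params$alpha * params$r_mean *
    (S(load_hi, geom$ms2_start, geom$ms2_end) -
       S(load_lo, geom$ms2_start, geom$ms2_end))
  pp7 <- params$pp7_basal + params$r_mean *
    (S(load_hi, geom$pp7_start, geom$pp7_end) -
       S(load_lo, geom$pp7_start, geom$pp7_end))
  tibble(time_min = times, ms2_au = ms2, pp7_au = pp7)
}
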