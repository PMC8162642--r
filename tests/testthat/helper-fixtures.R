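# Shared fixtures: a default reporter geometry, a typical parameter set, and
# an independent brute-force forward-model oracle (plain R sum over a very
# fine loading grid, built only from loop_fraction/transcript_signal).

default_geom <- function() reporter_geometry()

point_geom <- function() {
  reporter_geometry(gene_length = 5, ms2_start = 0, ms2_end = 0,
                    pp7_start = 1, pp7_end = 1)
}

default_params <- function(...) {
  transcription_params(r_mean = 15, v_elon = 1.7, tau_cleave = 2,
                       t_on = 1.5, alpha = 0.145, ms2_basal = 1,
                       pp7_basal = 2, ...)
}

# Brute-force Riemann-sum oracle for a constant-rate pulse, independent of
# the convolution kernel under test.
brute_force_pulse <- function(params, geom, times, t_off = Inf, dt = 0.001) {
  out <- vapply(times, function(t) {
    hi <- min(t, t_off)
    if (hi <= params$t_on) {
      return(c(params$ms2_basal, params$pp7_basal))
    }
    tp <- seq(params$t_on + dt / 2, hi, by = dt)
    age <- t - tp
    sm <- transcript_signal(age, params, geom, "MS2")
    sp <- transcript_signal(age, params, geom, "PP7")
    c(params$ms2_basal + params$alpha * params$r_mean * sum(sm) * dt,
      params$pp7_basal + params$r_mean * sum(sp) * dt)
  }, numeric(2))
  list(ms2 = out[1, ], pp7 = out[2, ])
}

random_pulse_params <- function() {
  transcription_params(
    r_mean = runif(1, 5, 30), v_elon = runif(1, 0.8, 3.5),
    tau_cleave = runif(1, 0.5, 4), t_on = runif(1, 0.5, 4),
    alpha = runif(1, 0.05, 0.3), ms2_basal = runif(1, 0, 3),
    pp7_basal = runif(1, 0, 5)
  )
}

fake_chain <- function(m) {
  structure(m, class = c("tx_chain", "matrix", "array"))
}
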