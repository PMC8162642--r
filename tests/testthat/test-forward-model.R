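test_that("loop_fraction ramps linearly across the cassette", {
  expect_equal(loop_fraction(0.0, 0.5, 1.5), 0)
  expect_equal(loop_fraction(1.0, 0.5, 1.5), 0.5)
  expect_equal(loop_fraction(2.0, 0.5, 1.5), 1)
  # vectorized, clamped
  expect_equal(loop_fraction(c(-1, 0.5, 0.75, 1.5, 9), 0.5, 1.5),
               c(0, 0, 0.25, 1, 1))
  # point cassette is a step
  expect_equal(loop_fraction(c(0.9, 1, 1.1), 1, 1), c(0, 1, 1))
  expect_error(loop_fraction(1, 2, 1), "cassette_start")
})

test_that("transcript_signal follows the polymerase and vanishes at cleavage", {
  g <- reporter_geometry(gene_length = 5, ms2_start = 0, ms2_end = 0,
                         pp7_start = 3, pp7_end = 3.5)
  p <- transcription_params(r_mean = 10, v_elon = 2, tau_cleave = 1.5)
  # head at 3.25 kb: halfway through the PP7 cassette
  expect_equal(transcript_signal(1.625, p, g, "PP7"), 0.5)
  # not yet at the PP7 cassette
  expect_equal(transcript_signal(1.0, p, g, "PP7"), 0)
  # cleaved: t_end = 5/2 + 1.5 = 4 min
  expect_equal(transcript_signal(4.0, p, g, "PP7"), 0)
  expect_equal(transcript_signal(4.0, p, g, "MS2"), 0)
  # during the cleavage wait the full cassette signal persists
  expect_equal(transcript_signal(3.9, p, g, "PP7"), 1)
  expect_error(transcript_signal(-0.1, p, g, "PP7"), "age")
})

test_that("predict_traces reproduces the analytic plateau of a constant pulse", {
  g <- point_geom()  # point cassettes: MS2 at 0, PP7 at d = 1 kb
  p <- transcription_params(r_mean = 10, v_elon = 2, tau_cleave = 1.5,
                            t_on = 1, alpha = 0.15, knot_window = c(0, 30))
  tt <- seq(0, 30, by = 0.25)
  pred <- predict_traces(p, g, tt)
  # before onset: basal only
  expect_equal(pred$ms2_au[tt < 1], rep(0, sum(tt < 1)))
  expect_equal(pred$pp7_au[tt < 1], rep(0, sum(tt < 1)))
  # plateaus: pp7 = R (L/v + tau - d/v) = 35; ms2 = alpha R (L/v + tau) = 6
  expect_equal(tail(pred$pp7_au, 1), 35, tolerance = 1e-9)
  expect_equal(tail(pred$ms2_au, 1), 6, tolerance = 1e-9)
  # independent brute-force oracle on a 0.001-min loading grid
  bf <- brute_force_pulse(p, g, c(3, 5.2, 12, 25))
  pr <- predict_traces(p, g, c(3, 5.2, 12, 25))
  expect_equal(pr$ms2_au, bf$ms2, tolerance = 1e-3)
  expect_equal(pr$pp7_au, bf$pp7, tolerance = 1e-3)
})

test_that("dR knots and r_mean are an equivalent parameterization", {
  g <- default_geom()
  tt <- seq(0, 18, by = 0.25)
  p1 <- transcription_params(r_mean = 10, dr_knots = rep(2, 5), v_elon = 1.7,
                             tau_cleave = 2, t_on = 1.5, alpha = 0.145)
  p2 <- transcription_params(r_mean = 12, dr_knots = rep(0, 5), v_elon = 1.7,
                             tau_cleave = 2, t_on = 1.5, alpha = 0.145)
  expect_equal(predict_traces(p1, g, tt), predict_traces(p2, g, tt),
               tolerance = 1e-12)
})

test_that("predict_traces rejects degenerate inputs", {
  g <- default_geom()
  p <- default_params()
  expect_error(predict_traces(p, g, numeric(0)), "empty")
  expect_error(predict_traces(p, g, c(1, 1, 2)), "increasing")
  p_bad <- p
  p_bad$r_mean <- NaN
  expect_error(predict_traces(p_bad, g, 1:5), "finite")
})

test_that("trapezoid breakpoints match the transcription-cycle timing", {
  g <- default_geom()
  p <- default_params()
  tt <- seq(0, 18, by = 0.001)
  cf <- trapezoid_closed_form(p, g, tt)
  # PP7 first exceeds basal at t_on + pp7_start / v_elon
  t_pp7 <- tt[which(cf$pp7_au > p$pp7_basal + 1e-9)[1]]
  expect_equal(t_pp7, p$t_on + g$pp7_start / p$v_elon, tolerance = 2e-3)
  # MS2 rises immediately after onset (cassette at the promoter)
  t_ms2 <- tt[which(cf$ms2_au > p$ms2_basal + 1e-9)[1]]
  expect_equal(t_ms2, p$t_on, tolerance = 2e-3)
  # plateau from t_on + L/v + tau onwards (point cassettes: exact corner)
  gp <- point_geom()
  pp <- transcription_params(r_mean = 10, v_elon = 2, tau_cleave = 1.5,
                             t_on = 1, alpha = 0.15)
  t_plat <- pp$t_on + gp$gene_length / pp$v_elon + pp$tau_cleave
  cf2 <- trapezoid_closed_form(pp, gp, c(t_plat - 0.01, t_plat, 17))
  expect_lt(cf2$pp7_au[1], cf2$pp7_au[2])
  expect_equal(cf2$pp7_au[2], cf2$pp7_au[3])
  expect_equal(cf2$ms2_au[2], cf2$ms2_au[3])
  expect_error(trapezoid_closed_form(p, g, tt, t_off = p$t_on), "t_off")
})

test_that("closed form and numeric forward model agree on random draws", {
  set.seed(421)
  g <- default_geom()
  tt <- seq(0, 18, by = 0.25)
  for (k in 1:25) {
    p <- random_pulse_params()
    pr <- predict_traces(p, g, tt)
    cf <- trapezoid_closed_form(p, g, tt)
    expect_lt(max(abs(pr$pp7_au - cf$pp7_au)) / max(cf$pp7_au), 1e-3)
    expect_lt(max(abs(pr$ms2_au - cf$ms2_au)) / max(cf$ms2_au), 1e-3)
  }
})

test_that("a finite pulse shuts off 5' before 3' and matches brute force", {
  g <- default_geom()
  p <- default_params()
  tt <- seq(0, 18, by = 0.01)
  cf <- trapezoid_closed_form(p, g, tt, t_off = 8)
  # after shut-off the MS2 signal starts decreasing before the PP7 signal
  i_ms2 <- which(diff(cf$ms2_au) < -1e-9)[1]
  i_pp7 <- which(diff(cf$pp7_au) < -1e-9)[1]
  expect_lt(tt[i_ms2], tt[i_pp7])
  bf <- brute_force_pulse(p, g, c(3, 6, 9, 11, 14, 17), t_off = 8)
  cf2 <- trapezoid_closed_form(p, g, c(3, 6, 9, 11, 14, 17), t_off = 8)
  expect_equal(cf2$ms2_au, bf$ms2, tolerance = 1e-2)
  expect_equal(cf2$pp7_au, bf$pp7, tolerance = 1e-2)
})

test_that("forward-model invariants: monotone rise, linearity, channel order", {
  set.seed(77)
  g <- default_geom()
  tt <- seq(0, 18, by = 0.25)
  for (k in 1:10) {
    p <- random_pulse_params()
    pred <- predict_traces(p, g, tt)
    # monotone non-decreasing before the first cleavage
    rise <- tt <= p$t_on + g$gene_length / p$v_elon + p$tau_cleave
    expect_true(all(diff(pred$ms2_au[rise]) >= -1e-9))
    expect_true(all(diff(pred$pp7_au[rise]) >= -1e-9))
    # doubling r_mean doubles the signal above basal
    p2 <- p
    p2$r_mean <- 2 * p$r_mean
    pred2 <- predict_traces(p2, g, tt)
    expect_equal(pred2$pp7_au - p$pp7_basal,
                 2 * (pred$pp7_au - p$pp7_basal), tolerance = 1e-9)
    # the 5' MS2 cassette is always ahead of the 3' PP7 cassette
    expect_true(all(pred$ms2_au - p$ms2_basal >=
                      p$alpha * (pred$pp7_au - p$pp7_basal) - 1e-9))
  }
})

test_that("geometry and parameter constructors enforce their invariants", {
  expect_error(reporter_geometry(gene_length = -1), "gene_length")
  expect_error(reporter_geometry(ms2_start = 2, ms2_end = 1), "cassette")
  expect_error(reporter_geometry(pp7_end = 9), "cassette")
  expect_error(transcription_params(r_mean = -1, v_elon = 1, tau_cleave = 1),
               "r_mean")
  expect_error(transcription_params(r_mean = 1, v_elon = 0, tau_cleave = 1),
               "v_elon")
  expect_error(transcription_params(r_mean = 1, dr_knots = rep(-2, 5),
                                    v_elon = 1, tau_cleave = 1),
               "initiation rate")
  expect_error(tx_trace(c(1, 1, 2), 1:3, 1:3), "increasing")
  expect_error(tx_trace(1:3, c(-1, 1, 2), 1:3), "fluorescence")
})
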