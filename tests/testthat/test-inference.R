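test_that("log_likelihood matches Gaussian algebra and a brute-force loop", {
  g <- default_geom()
  p <- default_params()
  tt <- seq(0, 18, by = 0.25)
  pred <- predict_traces(p, g, tt)
  sds <- c(0.5, 2)
  n <- length(tt)
  # observed == predicted: maximal value -sum log(sqrt(2 pi) sigma)
  tr0 <- tx_trace(tt, pred$ms2_au, pred$pp7_au)
  lmax <- -n * (log(sqrt(2 * pi) * sds[1]) + log(sqrt(2 * pi) * sds[2]))
  expect_equal(log_likelihood(p, tr0, g, sds), lmax)
  # one residual of exactly one sigma costs exactly 0.5
  ms2_off <- pred$ms2_au
  ms2_off[10] <- ms2_off[10] + sds[1]
  tr1 <- tx_trace(tt, ms2_off, pred$pp7_au)
  expect_equal(log_likelihood(p, tr1, g, sds), lmax - 0.5)
  # random trace equals an independent per-point sum
  set.seed(5)
  ms2 <- pmax(pred$ms2_au + rnorm(n, 0, 1), 0)
  pp7 <- pmax(pred$pp7_au + rnorm(n, 0, 3), 0)
  pp7[c(4, 40)] <- NA   # missing values contribute nothing
  tr2 <- tx_trace(tt, ms2, pp7)
  by_hand <- 0
  for (i in seq_len(n)) {
    by_hand <- by_hand + dnorm(ms2[i], pred$ms2_au[i], sds[1], log = TRUE)
    if (!is.na(pp7[i])) {
      by_hand <- by_hand + dnorm(pp7[i], pred$pp7_au[i], sds[2], log = TRUE)
    }
  }
  expect_equal(log_likelihood(p, tr2, g, sds), by_hand)
  # degenerate inputs
  expect_error(log_likelihood(p, tr0, g, c(0, 1)), "noise_sd")
  tr_all_na <- tx_trace(tt, rep(NA_real_, n), rep(NA_real_, n))
  expect_error(log_likelihood(p, tr_all_na, g, sds), "no data")
})

test_that("log_prior is a box plus a Gaussian penalty on the dR knots", {
  b <- default_bounds()
  p <- default_params()
  expect_equal(log_prior(p, b, dr_penalty_sd = 1), 0)
  p_lo <- p
  p_lo$v_elon <- 0.05   # below the lower bound of 0.1 kb/min
  expect_identical(log_prior(p_lo, b), -Inf)
  p_dr <- default_params(dr_knots = c(2, 0, 0, 0, 0))
  expect_equal(log_prior(p_dr, b, dr_penalty_sd = 1), -2)
  # positivity invariant: r_mean + dR >= 0 at every knot
  p_neg <- p
  p_neg$dr_knots <- c(-14.9, 0, 0, 0, 0)
  p_neg$r_mean <- 10
  expect_identical(log_prior(p_neg, b), -Inf)
})

test_that("identical seeds give bitwise-identical chains", {
  g <- default_geom()
  tr <- generate_trace(default_params(), g, seed = 3)
  cfg <- tc_inference_config(n_steps = 400, n_adapt = 50, seed = 17)
  ch1 <- run_mcmc(tr, g, cfg)
  ch2 <- run_mcmc(tr, g, cfg)
  expect_identical(unclass(ch1)[, ], unclass(ch2)[, ])
  expect_identical(attr(ch1, "log_posterior"), attr(ch2, "log_posterior"))
  expect_gt(attr(ch1, "acceptance_rate"), 0)
  expect_lt(attr(ch1, "acceptance_rate"), 1)
})

test_that("run_mcmc enforces its preconditions", {
  g <- default_geom()
  tr <- generate_trace(default_params(), g, seed = 3)
  short <- dplyr::slice_head(tr, n = 10)
  expect_error(run_mcmc(short, g), "non-missing points")
  two_cells <- dplyr::bind_rows(tr, dplyr::mutate(tr, cell_id = "cell_2"))
  expect_error(run_mcmc(two_cells, g), "one cell")
})

test_that("a noiseless trace is recovered to within 1% under tight bounds", {
  g <- default_geom()
  truth <- default_params()
  tr <- generate_trace(truth, g, noise_sd = c(1e-6, 1e-6), seed = 3)
  b <- default_bounds(tr)
  b$v_elon <- c(1.2, 2.2)
  b$tau_cleave <- c(1, 3)
  b$r_mean <- c(10, 20)
  b$alpha <- c(0.1, 0.2)
  cfg <- tc_inference_config(n_steps = 4000, noise_sd = c(0.05, 0.2),
                             bounds = b, seed = 11)
  fit <- summarize_chain(run_mcmc(tr, g, cfg))
  m <- setNames(fit$mean, fit$parameter)
  expect_lt(abs(m[["r_mean"]] - truth$r_mean) / truth$r_mean, 0.01)
  expect_lt(abs(m[["v_elon"]] - truth$v_elon) / truth$v_elon, 0.01)
  expect_lt(abs(m[["tau_cleave"]] - truth$tau_cleave) / truth$tau_cleave, 0.01)
})

test_that("summarize_chain reports means, sds and central intervals", {
  # constant chain
  const <- fake_chain(matrix(3, nrow = 50, ncol = 2,
                             dimnames = list(NULL, c("a", "b"))))
  s <- summarize_chain(const, burn_in_fraction = 0)
  expect_equal(s$mean, c(3, 3))
  expect_equal(s$sd, c(0, 0))
  # large standard-normal chain
  set.seed(8)
  z <- fake_chain(matrix(rnorm(1e5), ncol = 1, dimnames = list(NULL, "z")))
  sz <- summarize_chain(z, burn_in_fraction = 0, ci_level = 0.9)
  expect_equal(sz$mean, 0, tolerance = 0.01)
  expect_equal(sz$sd, 1, tolerance = 0.01)
  expect_equal(sz$ci_lo, qnorm(0.05), tolerance = 0.05)
  # burn-in bookkeeping: half of 1000 steps leaves exactly 500
  m <- fake_chain(matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "x")))
  s2 <- summarize_chain(m, burn_in_fraction = 0.5)
  expect_identical(attr(s2, "n_kept"), 500L)
  expect_error(summarize_chain(m, burn_in_fraction = 1), "burn_in_fraction")
})

test_that("chain autocorrelation is 1 at lag 0 and tracks AR(1) memory", {
  set.seed(9)
  wn <- fake_chain(matrix(rnorm(1e4), ncol = 1, dimnames = list(NULL, "w")))
  a <- chain_autocorrelation(wn, max_lag = 20)
  expect_equal(a$acf[a$lag == 0], 1)
  expect_true(all(abs(a$acf[a$lag >= 1]) < 0.05))
  # AR(1) with coefficient 0.9: ACF(k) = 0.9^k
  x <- as.numeric(arima.sim(list(ar = 0.9), n = 2e4))
  ar <- fake_chain(matrix(x, ncol = 1, dimnames = list(NULL, "x")))
  aa <- chain_autocorrelation(ar, max_lag = 3)
  expect_equal(aa$acf[aa$lag == 1], 0.9, tolerance = 0.03)
  expect_equal(aa$acf[aa$lag == 2], 0.81, tolerance = 0.05)
  flat <- fake_chain(matrix(1, nrow = 100, ncol = 1,
                            dimnames = list(NULL, "c")))
  expect_error(chain_autocorrelation(flat, 10), "degenerate")
  expect_error(chain_autocorrelation(wn, 1e5), "max_lag")
})

test_that("tidy and glance methods return well-formed tibbles", {
  g <- default_geom()
  tr <- generate_trace(default_params(), g, seed = 3)
  ch <- run_mcmc(tr, g, tc_inference_config(n_steps = 400, n_adapt = 50,
                                            seed = 1))
  td <- tidy(ch)
  expect_true(all(c("parameter", "mean", "sd", "ci_lo", "ci_hi") %in%
                    names(td)))
  expect_true("r_mean" %in% td$parameter)
  gl <- glance(ch)
  expect_identical(gl$n_steps, 400L)
  fit <- summarize_chain(ch)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_true(is.numeric(glance(fit)$fit_quality))
  expect_lte(glance(fit)$fit_quality, 1)
})
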