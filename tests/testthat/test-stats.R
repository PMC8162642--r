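test_that("alpha fit through the origin recovers the slope", {
  pp7 <- seq(1, 50, length.out = 40)
  expect_equal(fit_alpha_through_origin(0.154 * pp7, pp7)$alpha, 0.154)
  expect_equal(fit_alpha_through_origin(c(1, 2), c(1, 2))$alpha, 1)
  # symmetric noise about a slope-s line: slope recovered within its SE
  set.seed(14)
  s <- 0.145
  pp7n <- runif(1e4, 10, 60)
  ms2n <- s * pp7n + rnorm(1e4, 0, 0.5)
  fit <- fit_alpha_through_origin(ms2n, pp7n)
  expect_lt(abs(fit$alpha - s), 3 * fit$alpha_se)
  expect_equal(fit$ratio_mean, s, tolerance = 0.01)
  expect_error(fit_alpha_through_origin(1, 1), "2 paired")
  expect_error(fit_alpha_through_origin(c(1, 2), c(0, 0)), "zero")
})

test_that("cv2 decomposition is additive and separates noise sources", {
  # identical channels: no uncorrelated noise
  m <- c(1, 2, 3)
  d <- decompose_cv2(m, m)
  expect_equal(d$cv2_uncorrelated, 0)
  pop_var <- mean(m^2) - mean(m)^2
  expect_equal(d$cv2_total, pop_var / mean(m)^2)
  expect_equal(d$cv2_correlated, d$cv2_total)
  # additivity is exact on arbitrary inputs
  set.seed(15)
  for (k in 1:20) {
    a <- rlnorm(50, 1, 0.6)
    b <- rlnorm(50, 1, 0.6)
    dd <- decompose_cv2(a, b)
    expect_equal(dd$cv2_total, dd$cv2_correlated + dd$cv2_uncorrelated,
                 tolerance = 1e-12)
  }
  # independent channels: correlated component vanishes
  a <- rlnorm(1e5, 2, 0.3)
  b <- rlnorm(1e5, 2, 0.3)
  expect_lt(abs(decompose_cv2(a, b)$cv2_correlated), 0.01)
  expect_error(decompose_cv2(c(-2, 1), c(1, -2)), "positive")
})

test_that("interlaced-reporter logic recovers injected noise components", {
  # two noisy measurements of one biological signal: the uncorrelated
  # component estimates the measurement CV^2, the correlated component the
  # biological CV^2
  set.seed(16)
  n <- 4000
  cv_bio <- 0.3
  cv_meas <- 0.15
  bio <- 20 * (1 + rnorm(n, 0, cv_bio))
  m <- bio * (1 + rnorm(n, 0, cv_meas))
  p <- bio * (1 + rnorm(n, 0, cv_meas))
  d <- decompose_cv2(m, p)
  expect_equal(d$cv2_uncorrelated, cv_meas^2, tolerance = 0.1)
  expect_equal(d$cv2_correlated, cv_bio^2, tolerance = 0.1)
})

test_that("bootstrap_cv matches hand arithmetic and is seeded", {
  const <- bootstrap_cv(rep(2, 10), seed = 1)
  expect_equal(const$cv, 0)
  expect_equal(const$se, 0)
  expect_equal(bootstrap_cv(c(1, 3), seed = 1)$cv, sqrt(2) / 2)
  x <- rlnorm(30, 1, 0.4)
  expect_identical(bootstrap_cv(x, seed = 7), bootstrap_cv(x, seed = 7))
  sq <- bootstrap_cv(x, seed = 7, squared = TRUE)
  expect_equal(sq$cv2, (sd(x) / mean(x))^2)
  expect_error(bootstrap_cv(c(1)), "n >= 2")
  expect_error(bootstrap_cv(c(-1, 1)), "mean")
})

test_that("spearman matches rank arithmetic", {
  x <- 1:10
  expect_equal(spearman(x, x^3)$rho, 1)
  expect_equal(spearman(x, -x^3)$rho, -1)
  s <- spearman(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(s$rho, 0.8)
  expect_gt(s$p_value, 0.05)   # n = 4: far from significant
  # matches the rank-based Pearson formula under ties
  set.seed(17)
  a <- sample(1:5, 30, replace = TRUE)
  b <- a + sample(1:3, 30, replace = TRUE)
  expect_equal(spearman(a, b)$rho, cor(rank(a), rank(b)))
  expect_error(spearman(1:2, 2:3), "n >= 3")
  expect_error(spearman(rep(1, 5), 1:5), "constant")
})

test_that("density and occupancy arithmetic", {
  expect_equal(transcript_density(20, 2), 10)
  expect_equal(transcript_density(0, 2), 0)
  expect_equal(transcript_density(30, 3), transcript_density(60, 6))
  expect_error(transcript_density(1, 0), "v_elon")
  expect_equal(occupancy_fraction(20, 40), 0.8)
  expect_equal(occupancy_fraction(0, 40), 0)
  expect_equal(occupancy_fraction(25, 40), 1)   # capped at full occupancy
  expect_error(occupancy_fraction(-1), "density")
})

test_that("AP binning reports per-bin means, SEMs and CVs", {
  res <- tibble::tibble(
    cell_id = paste0("c", 1:6),
    ap_position = c(0.1, 0.15, 0.2, 0.6, 0.65, 0.7),
    r_mean = c(10, 12, 14, 2, 4, 6),
    v_elon = c(1.5, 1.7, 1.9, 1.6, 1.8, 2.0)
  )
  # one big bin: bin mean equals the global mean
  one <- bin_by_position(res, bin_edges = c(0, 1), params = "r_mean")
  expect_equal(one$mean, mean(res$r_mean))
  expect_equal(one$n, 6L)
  # two bins with hand-computed summaries
  two <- bin_by_position(res, bin_edges = c(0, 0.5, 1), params = "r_mean")
  expect_equal(two$mean, c(12, 4))
  expect_equal(two$sem, c(2, 2) / sqrt(3))
  expect_equal(two$bin_mid, c(0.25, 0.75))
  # duplicating every cell shrinks the SEM roughly as 1/sqrt(n)
  dup <- dplyr::bind_rows(res, dplyr::mutate(res, cell_id = paste0(cell_id, "b")))
  two_dup <- bin_by_position(dup, bin_edges = c(0, 0.5, 1), params = "r_mean")
  expect_equal(two_dup$sem[1], sd(c(10, 10, 12, 12, 14, 14)) / sqrt(6))
  expect_equal(two_dup$sem / two$sem, rep(1 / sqrt(2), 2), tolerance = 0.15)
  expect_error(bin_by_position(dplyr::select(res, -ap_position)),
               "ap_position")
})

test_that("posterior-propagation Monte Carlo handles point and full chains", {
  mk <- function(vals) fake_chain(vals)
  # degenerate single-row chains: every draw equals the point-estimate rho
  cells <- lapply(1:6, function(i) {
    m <- matrix(c(i, 7 - i), nrow = 1,
                dimnames = list(NULL, c("r_mean", "v_elon")))
    mk(m)
  })
  out <- posterior_correlation_mc(cells, "r_mean", "v_elon", n_draws = 20,
                                  burn_in_fraction = 0, seed = 3)
  expect_true(all(out$draws$rho == out$draws$rho[1]))
  expect_equal(out$draws$rho[1], -1)
  # independent chains with independent centers: interval close to 0
  set.seed(18)
  cells2 <- lapply(1:60, function(i) {
    m <- cbind(r_mean = rnorm(200, rnorm(1, 15, 3), 0.5),
               v_elon = rnorm(200, rnorm(1, 1.7, 0.3), 0.05))
    mk(m)
  })
  out2 <- posterior_correlation_mc(cells2, "r_mean", "v_elon",
                                   n_draws = 100, seed = 4)
  expect_lte(out2$summary$ci_lo, 0.3)
  expect_gte(out2$summary$ci_hi, -0.3)
  # seeded reproducibility, and the density pseudo-parameter works
  d1 <- posterior_correlation_mc(cells2, "density", "v_elon", n_draws = 30,
                                 seed = 9)
  d2 <- posterior_correlation_mc(cells2, "density", "v_elon", n_draws = 30,
                                 seed = 9)
  expect_identical(d1$draws, d2$draws)
})
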