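# Smooth back-calculation: kernel regression, bandwidth selection,
# ODE inversion, variance estimation and the bootstrap pipeline.

test_that("local-linear smooth reproduces constants and straight lines exactly", {
  tt <- seq(0, 10, by = 0.5)
  for (h in c(0.5, 2, 5)) {
    fc <- kernel_smooth(tt, rep(3.7, length(tt)), h)
    expect_equal(fc$predict(seq(1, 9, by = 0.3)), rep(3.7, 27), tolerance = 1e-10)
    expect_equal(fc$derivative(seq(1, 9, by = 0.3)), rep(0, 27), tolerance = 1e-10)
    fl <- kernel_smooth(tt, 2 - 0.8 * tt, h)
    expect_equal(fl$predict(tt), 2 - 0.8 * tt, tolerance = 1e-10)
    expect_equal(fl$derivative(tt), rep(-0.8, length(tt)), tolerance = 1e-10)
  }
})

test_that("smooth at a point matches a brute-force weighted least-squares fit", {
  set.seed(501)
  tt <- sort(runif(40, 0, 12))
  yy <- sin(tt) + rnorm(40, 0, 0.3)
  fit <- kernel_smooth(tt, yy, 1.2)
  for (t0 in c(2.3, 6.05, 9.9)) {
    oracle <- lm_local_fit(tt, yy, 1.2, t0)
    expect_equal(fit$predict(t0), oracle$value, tolerance = 1e-9)
    expect_equal(fit$derivative(t0), oracle$deriv, tolerance = 1e-9)
  }
  expect_error(kernel_smooth(tt, yy, 0), "positive")
  expect_error(kernel_smooth(tt[1:4], yy[1:4], 1), "at least 5")
})

test_that("LOOCV bandwidth matches a brute-force grid search and tie-breaks up", {
  tt <- seq(0, 10, length.out = 21)
  cand <- c(0.5, 1, 2, 4)
  # noiseless linear data: all candidates perfect, tie goes to the largest
  expect_equal(loocv_bandwidth(tt, 1 + 2 * tt, cand), 4)

  set.seed(502)
  yy <- sin(tt) + rnorm(21, 0, 0.2)
  sel <- loocv_bandwidth(tt, yy, cand)
  oracle <- cand[which.min(lm_loocv_scores(tt, yy, cand))]
  expect_equal(sel, oracle)

  # duplicating every point as a second replicate leaves the selection
  # unchanged when whole time points are held out
  expect_equal(loocv_bandwidth(c(tt, tt), c(yy, yy), cand), sel)
})

test_that("back-calculation inverts the kinetic equations", {
  tt <- seq(0, 10, by = 0.05)
  cfit <- kernel_smooth(tt, rep(4, length(tt)), 0.5)
  expect_equal(back_calculate_mrna(cfit, 0.3, seq(1, 9, by = 0.5)),
               rep(1.2, 17), tolerance = 1e-8)
  expect_equal(back_calculate_transcription(cfit, 2, seq(1, 9, by = 0.5)),
               rep(8, 17), tolerance = 1e-8)

  # P(t) = sin t with delta_P = 1 gives M(t) = cos t + sin t; tolerance
  # reflects the O(h^2) kernel attenuation of a unit-frequency sinusoid
  sfit <- kernel_smooth(tt, sin(tt), 0.15)
  grid <- seq(1, 9, by = 0.1)
  expect_equal(back_calculate_mrna(sfit, 1, grid), cos(grid) + sin(grid),
               tolerance = 2e-2)

  # near-exact exponential fit back-calculates to ~0 mRNA
  efit <- kernel_smooth(tt, exp(-0.4 * tt), 0.1)
  expect_lt(max(abs(back_calculate_mrna(efit, 0.4, grid))), 1e-3)
})

test_that("noiseless synthetic protein round-trips to the true transcription", {
  spec <- synthetic_spec(profile = function(t) 1 + 0.8 * sin(2 * pi * t / 24),
                         horizon = 90, delta_M = 2.3, delta_P = 0.13,
                         times = seq(0, 90, by = 0.25), replicates = 1,
                         profile_type = "protein", name = "rt")
  pl <- simulate_dataset(spec)$series
  x <- pl$times[[1]]; y <- pl$values[[1]]
  h <- loocv_bandwidth(x, y)
  grid <- seq(0, 90, by = 0.05)
  M <- back_calculate_mrna(kernel_smooth(x, y, h), 0.13, grid)
  tau <- back_calculate_transcription(M, 2.3, grid, bandwidth = 0.1)
  truth <- 1 + 0.8 * sin(2 * pi * grid / 24)
  interior <- grid >= 9 & grid <= 81
  expect_lt(max((abs(tau - truth) / abs(truth))[interior]), 0.05)
})

test_that("variance function tracks the residual scale", {
  tt <- seq(0, 20, length.out = 60)
  s2_zero <- estimate_variance_function(tt, rep(0, 60), 2)
  expect_true(all(s2_zero(tt) > 0))
  expect_lt(max(s2_zero(tt)), 1e-10)

  # linearly increasing |residuals| -> monotone variance on the interior
  set.seed(503)
  res_inc <- (0.1 + 0.2 * tt) * sign(rnorm(60))
  s2_inc <- estimate_variance_function(tt, res_inc, 3)
  v <- s2_inc(seq(4, 16, by = 1))
  expect_true(all(diff(v) > 0))

  # homoscedastic residuals recovered within 30% on the interior
  res_hom <- rnorm(60, 0, 0.5)
  s2_hom <- estimate_variance_function(tt, res_hom, 4)
  expect_true(all(abs(s2_hom(seq(4, 16, by = 1)) - 0.25) < 0.3 * 0.25 + 0.05))
})

test_that("bootstrap resampling preserves residual signs and half-normal scale", {
  set.seed(504)
  tt <- seq(0, 12, length.out = 30)
  yy <- 5 + sin(tt) + rnorm(30, 0, 0.4)
  fit <- kernel_smooth(tt, yy, 1.5)
  sigma2 <- estimate_variance_function(tt, fit$residuals, 1.5)
  for (i in 1:20) {
    e <- bootstrap_resample(fit, sigma2) - fit$fitted
    expect_true(all(sign(e) == sign(fit$residuals) | e == 0))
  }
  # degenerate variance reproduces the fit exactly
  expect_equal(bootstrap_resample(fit, function(t) rep(0, length(t))), fit$fitted)
  # E|e| = sigma * sqrt(2/pi)
  draws <- replicate(4000, abs(bootstrap_resample(fit, sigma2) - fit$fitted))
  expect_equal(rowMeans(draws), sqrt(sigma2(tt)) * sqrt(2 / pi), tolerance = 0.05)
})

test_that("run_smooth stores R runs with ordered envelopes and collapses without noise", {
  fx <- standard_fixtures(seed = 7)$circadian_protein
  priors <- kinetic_priors(2.3, 0.46, 0.13, 0.010)
  res <- run_smooth(fx$series, priors, R = 99, seed = 1)
  expect_equal(nrow(res$tau_runs), 99)
  expect_equal(length(res$delta_M_draws), 99)
  expect_true(all(res$tau$lower <= res$tau$mean + 1e-12) &&
                all(res$tau$mean <= res$tau$upper + 1e-12))
  expect_true(all(res$M$lower <= res$M$upper))

  # zero observation noise + near-point-mass priors: envelope width ~ 0
  fx0 <- standard_fixtures(seed = 7, noise = 0)$circadian_protein
  tight <- kinetic_priors(2.3, 1e-8, 0.13, 1e-8)
  res0 <- run_smooth(fx0$series, tight, R = 30, seed = 2)
  rel_width <- max(res0$tau$upper - res0$tau$lower) / max(abs(res0$tau$mean))
  # residual variance is floored at 1e-12 * max(fit)^2, and differentiation
  # amplifies that floor, so "zero" width means ~1e-3 of the signal scale
  expect_lt(rel_width, 1e-2)
})

test_that("reconstruction is scale-equivariant", {
  fx <- standard_fixtures(seed = 9)$circadian_protein
  s <- fx$series
  priors <- kinetic_priors(2.3, 0.46, 0.13, 0.010)
  r1 <- run_smooth(s, priors, R = 20, seed = 5)
  s2 <- s; s2$values <- lapply(s$values, function(v) 10 * v)
  r2 <- run_smooth(s2, priors, R = 20, seed = 5)
  expect_equal(r2$bandwidth, r1$bandwidth)
  expect_equal(r2$tau$mean, 10 * r1$tau$mean, tolerance = 1e-8)
  expect_equal(r2$M$upper, 10 * r1$M$upper, tolerance = 1e-8)
})

test_that("mRNA-mode pipeline applies the single back-calculation step", {
  fx <- standard_fixtures(seed = 11)$two_switch_mrna
  priors <- kinetic_priors(1.5, 1e-9)   # point-mass delta_M
  res <- run_smooth(fx$series, priors, R = 10, seed = 3)
  expect_true(all(is.na(res$delta_P_draws)))
  # with a point-mass prior, tau must equal dM/dt + delta_M * M for the
  # stored smooth of each run
  pl <- txrecon:::pool_series(fx$series)
  fit <- kernel_smooth(pl$times, pl$values, res$bandwidth)
  tau_direct <- back_calculate_transcription(fit, 1.5, res$grid)
  M_direct <- fit$predict(res$grid)
  expect_equal(tau_direct, M_direct * 1.5 + fit$derivative(res$grid),
               tolerance = 1e-10)
})
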