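# Switch-model inference: regression, weights, likelihood, sampler
# behaviour and posterior summaries.

test_that("fit_regression matches the normal equations and handles weights", {
  set.seed(601)
  X <- cbind(1, rnorm(30), rnorm(30))
  beta <- c(2, -1, 0.5)
  y_exact <- drop(X %*% beta)
  f <- fit_regression(X, y_exact)
  expect_equal(f$betas, beta, tolerance = 1e-10)
  expect_equal(f$rss, 0, tolerance = 1e-18)

  y <- y_exact + rnorm(30, 0, 0.3)
  f1 <- fit_regression(X, y)
  f2 <- fit_regression(X, y, weights = rep(1, 30))
  expect_equal(f1$betas, f2$betas)
  oracle <- drop(solve(crossprod(X), crossprod(X, y)))
  expect_equal(f1$betas, oracle, tolerance = 1e-8)

  w <- runif(30, 0.5, 2)
  fw <- fit_regression(X, y, weights = w)
  oracle_w <- drop(solve(crossprod(X * w, X), crossprod(X * w, y)))
  expect_equal(fw$betas, oracle_w, tolerance = 1e-8)

  # rank-deficient design signals a degenerate configuration
  expect_null(fit_regression(cbind(X, X[, 2]), y))
})

test_that("spline weights trace expression level and stay positive", {
  tt <- seq(0, 24, length.out = 25)
  s_const <- expression_series("c", tt, rep(5, 25), "mRNA")
  expect_equal(spline_weights(s_const), rep(5, 25), tolerance = 1e-6)

  set.seed(602)
  s_sin <- expression_series("s", tt, 3 + 2 * sin(tt / 3) + rnorm(25, 0, 0.1), "mRNA")
  w <- spline_weights(s_sin)
  expect_true(all(w > 0))
  expect_equal(w, 3 + 2 * sin(tt / 3), tolerance = 0.15)
})

test_that("log-likelihood matches the Gaussian closed form", {
  expect_equal(log_likelihood(0, 0, 1), -0.5 * log(2 * pi))
  set.seed(603)
  y <- rnorm(12); mu <- rnorm(12)
  # with zero residuals, doubling sigma^2 lowers the log-likelihood by n/2 log 2
  expect_equal(log_likelihood(y, y, 1) - log_likelihood(y, y, 2), 6 * log(2))
  s2 <- 0.7
  manual <- -length(y) / 2 * log(2 * pi * s2) - sum((y - mu)^2) / (2 * s2)
  expect_equal(log_likelihood(y, mu, s2), manual)
  w <- runif(12, 0.5, 2)
  manual_w <- -length(y) / 2 * log(2 * pi * s2) + sum(log(w)) / 2 -
    sum(w * (y - mu)^2) / (2 * s2)
  expect_equal(log_likelihood(y, mu, s2, w), manual_w)
  expect_error(log_likelihood(y, mu, 0), "positive")
})

test_that("identical seeds give bit-identical chains", {
  fx <- standard_fixtures(seed = 3)$two_switch_mrna
  priors <- kinetic_priors(1.5, 0.18)
  c1 <- run_switch(fx$series, priors, iterations = 2000, seed = 99)
  c2 <- run_switch(fx$series, priors, iterations = 2000, seed = 99)
  expect_identical(c1$k, c2$k)
  expect_identical(c1$delta_M, c2$delta_M)
  expect_identical(c1$sigma2, c2$sigma2)
  expect_identical(c1$s, c2$s)
})

test_that("mRNA mode never updates delta_P and thins storage correctly", {
  fx <- standard_fixtures(seed = 3)$two_switch_mrna
  priors <- kinetic_priors(1.5, 0.18)
  ch <- run_switch(fx$series, priors, iterations = 3000, thin = 10, seed = 4)
  expect_length(ch$k, 300)
  expect_true(all(is.na(ch$delta_P)))
  expect_equal(ch$burn_in, 60)   # 20% of 3000, in stored units
})

test_that("prior-only sampling reproduces the gamma prior on delta_M", {
  fx <- standard_fixtures(seed = 3)$null_mrna
  priors <- kinetic_priors(1.5, 0.18)
  ch <- run_switch(fx$series, priors, iterations = 15000, seed = 8,
                   prior_only = TRUE)
  post <- seq_along(ch$k) > ch$burn_in
  expect_equal(mean(ch$delta_M[post]), 1.5, tolerance = 0.03)
  expect_equal(sd(ch$delta_M[post]), 0.18, tolerance = 0.05)
})

test_that("fast-reporter protein mode agrees with mRNA mode on modal k", {
  # a near-instantaneous reporter (large delta_P) makes protein data a
  # scaled copy of the mRNA path, so both observation models should call
  # the same number of switches
  pr <- switch_profile(c(10, 20), c(5, 20, 5), horizon = 48)
  dP <- 8
  spec_p <- synthetic_spec(profile = pr, delta_M = 1.5, delta_P = dP,
                           times = seq(0, 48, length.out = 48), replicates = 3,
                           profile_type = "protein", sd = 0.06, name = "fastrep")
  sim <- simulate_dataset(spec_p, seed = 21)
  ch_p <- run_switch(sim$series, kinetic_priors(1.5, 0.18, dP, 0.01),
                     iterations = 12000, seed = 31)

  s_m <- sim$series
  s_m$profile_type <- "mRNA"
  s_m$values <- lapply(s_m$values, function(v) v * dP)
  ch_m <- run_switch(s_m, kinetic_priors(1.5, 0.18), iterations = 12000, seed = 32)

  modal <- function(ch) {
    kk <- ch$k[-seq_len(ch$burn_in)]
    as.integer(names(which.max(table(kk))))
  }
  expect_equal(modal(ch_p), modal(ch_m))
  expect_equal(modal(ch_m), 2L)
})

test_that("parameter summaries match order-statistics oracles", {
  ch <- fake_chains(k = rep(0L, 100), s = rep(list(numeric(0)), 100),
                    betas = rep(list(c(1, 2)), 100),
                    delta_M = seq(1, 2, length.out = 100), horizon = 48,
                    sigma2 = rep(3, 100))
  out <- summarize_parameters(ch)
  s2 <- out[out$parameter == "sigma2", ]
  expect_equal(unlist(s2[c("median", "q25", "q75", "mean", "lower95", "upper95")]),
               c(median = 3, q25 = 3, q75 = 3, mean = 3, lower95 = 3, upper95 = 3))
  dm <- out[out$parameter == "delta_M", ]
  x <- seq(1, 2, length.out = 100)
  expect_equal(dm$median, unname(quantile(x, 0.5)))
  expect_equal(dm$q25, unname(quantile(x, 0.25)))
  expect_equal(dm$mean, mean(x))
  expect_equal(dm$upper95, mean(x) + 1.96 * sd(x))
})

test_that("switch summaries call concentrated events and ignore diffuse ones", {
  set.seed(604)
  n <- 600
  # all samples k = 1 near s = 12, increasing rate
  s_list <- lapply(rnorm(n, 12, 0.1), function(v) v)
  b_list <- rep(list(c(1, 2, 3)), n)   # M0, tau0/dM, positive increment
  ch1 <- fake_chains(k = rep(1L, n), s = s_list, betas = b_list,
                     delta_M = rep(1.5, n), horizon = 48)
  sm1 <- summarize_switches(ch1)
  expect_equal(sm1$modal_k, 1L)
  expect_equal(nrow(sm1$mixture), 1L)
  expect_equal(sm1$mixture$mean, 12, tolerance = 0.05)
  expect_lt(sm1$mixture$sd, 0.3)
  expect_equal(sm1$mixture$direction, "increase")

  # switch times uniform on the horizon: baseline removal flattens density
  s_unif <- lapply(runif(n, 0, 48), function(v) v)
  ch2 <- fake_chains(k = rep(1L, n), s = s_unif, betas = b_list,
                     delta_M = rep(1.5, n), horizon = 48)
  sm2 <- summarize_switches(ch2)
  interior <- sm2$switch_density$time > 4 & sm2$switch_density$time < 44
  expect_lt(mean(sm2$switch_density$density[interior]), 0.35 * sm2$baseline)

  # all k = 0: empty mixture, histogram mass at 0
  ch0 <- fake_chains(k = rep(0L, n), s = rep(list(numeric(0)), n),
                     betas = rep(list(c(1, 2)), n),
                     delta_M = rep(1.5, n), horizon = 48)
  sm0 <- summarize_switches(ch0)
  expect_equal(nrow(sm0$mixture), 0L)
  expect_equal(sm0$modal_k, 0L)
  expect_equal(unname(sm0$model_size_histogram["0"]), n)
  expect_true(all(sm0$switch_density$density == 0))

  # decreasing event gets the decrease label
  b_dec <- rep(list(c(1, 10, -4)), n)
  ch3 <- fake_chains(k = rep(1L, n), s = s_list, betas = b_dec,
                     delta_M = rep(1.5, n), horizon = 48)
  expect_equal(summarize_switches(ch3)$mixture$direction, "decrease")
})

test_that("wls regression option runs and weights shift the fit", {
  fx <- standard_fixtures(seed = 5)$two_switch_mrna
  priors <- kinetic_priors(1.5, 0.18)
  ch <- run_switch(fx$series, priors, iterations = 4000, seed = 12,
                   regression = "wls")
  kk <- ch$k[-seq_len(ch$burn_in)]
  expect_equal(as.integer(names(which.max(table(kk)))), 2L)
})
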