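# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: the ODE oracle integrates numerically, the
# local-fit oracle goes through lm(), the LOOCV oracle is a plain loop.

# Adaptive-step numeric integration of the kinetic ODEs under a
# piecewise-constant (or functional) transcription rate.
ode_oracle <- function(M0, P0 = NULL, profile, delta_M, delta_P = NULL,
                       alpha = 1, times) {
  tau_at <- if (is.function(profile)) profile else
    function(t) profile$rates[findInterval(t, profile$switch_times,
                                           left.open = TRUE) + 1L]
  y0 <- c(M = M0, P = if (is.null(P0)) 0 else P0)
  out <- deSolve::ode(y0, times, function(t, y, p) {
    dM <- tau_at(t) - delta_M * y[1]
    dP <- if (is.null(delta_P)) 0 else alpha * y[1] - delta_P * y[2]
    list(c(dM, dP))
  }, NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  list(M = out[, "M"], P = out[, "P"])
}

# One-point local-linear fit via lm(): intercept = value, slope = derivative.
lm_local_fit <- function(x, y, h, t0) {
  w <- stats::dnorm((x - t0) / h)
  co <- stats::coef(stats::lm(y ~ I(x - t0), weights = w))
  list(value = unname(co[1]), deriv = unname(co[2]))
}

# Brute-force LOOCV score curve over a candidate grid, holding out whole
# time points, with lm-based local fits.
lm_loocv_scores <- function(x, y, candidates) {
  ut <- sort(unique(x))
  vapply(candidates, function(h) {
    err2 <- 0; n <- 0L
    for (t0 in ut) {
      keep <- x != t0
      pred <- lm_local_fit(x[keep], y[keep], h, t0)$value
      err2 <- err2 + sum((y[x == t0] - pred)^2)
      n <- n + sum(x == t0)
    }
    err2 / n
  }, numeric(1))
}

# Random switch profile with k switches on [0, L], minimum separation.
random_profile <- function(k, L, rate_max = 10, min_sep = L / 20) {
  repeat {
    s <- sort(stats::runif(k, min_sep, L - min_sep))
    if (k < 2 || all(diff(s) >= min_sep)) break
  }
  switch_profile(s, stats::runif(k + 1, 0.1, rate_max), L)
}

# Hand-built switch_chains object for summary tests.
fake_chains <- function(k, s, betas, delta_M, horizon, mode = "mRNA",
                        delta_P = rep(NA_real_, length(k)),
                        sigma2 = rep(1, length(k)), burn_in = 0L, kmax = 20L) {
  structure(list(k = k, s = s, betas = betas,
                 delta_M = delta_M, delta_P = delta_P, sigma2 = sigma2,
                 move = rep("relocate", length(k)),
                 accepted = rep(TRUE, length(k)),
                 iterations = length(k), thin = 1L, burn_in = as.integer(burn_in),
                 horizon = horizon, time_offset = 0, mode = mode,
                 kmax = as.integer(kmax), min_sep = 1, regression = "ols",
                 seed = NULL, name = "fake"),
            class = "switch_chains")
}
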