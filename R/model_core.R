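# Two-stage linear kinetic model
#
#   dM/dt = tau(t) - delta_M * M,   dP/dt = alpha * M - delta_P * P
#
# with tau(t) piecewise constant. Both the closed-form solutions and the
# linear-regression parameterisation used by the switch sampler live here.

# Stable (e^{-dM*u} - e^{-dP*u}) / (dP - dM), elementwise in u (u >= 0).
# Removable singularity at dP == dM; below `tol` relative difference a
# second-order series in d = dP - dM is used.
exp_diff_ratio <- function(u, delta_M, delta_P) {
  d <- delta_P - delta_M
  if (abs(d) < 1e-8 * max(delta_P, delta_M)) {
    # e^{-dM u} * u * (1 - d u / 2 + (d u)^2 / 6)
    du <- d * u
    exp(-delta_M * u) * u * (1 - du / 2 + du * du / 6)
  } else {
    # e^{-dM u} * (1 - e^{-d u}) / d, with expm1 to avoid cancellation
    exp(-delta_M * u) * (-expm1(-d * u)) / d
  }
}

#' Closed-form mRNA path under piecewise-constant transcription
#'
#' Propagates the exact piecewise-exponential solution of
#' `dM/dt = tau(t) - delta_M * M` segment by segment: within a segment of
#' constant rate tau, `M(t) = tau/delta_M + (M_s - tau/delta_M) *
#' exp(-delta_M * (t - t_s))`.
#'
#' @param M0 Initial mRNA level `M(0)` (non-negative).
#' @param profile A [switch_profile()].
#' @param delta_M mRNA decay rate (1/hour, strictly positive).
#' @param times Evaluation grid within `[0, horizon]`.
#'
#' @return Numeric vector `M(times)`.
#' @export
mrna_solution <- function(M0, profile, delta_M, times) {
  stopifnot(inherits(profile, "switch_profile"))
  if (length(delta_M) != 1L || !is.finite(delta_M) || delta_M <= 0)
    stop("`delta_M` must be a single strictly positive rate")
  if (any(times < 0 | times > profile$horizon))
    stop("`times` must lie within [0, horizon]")

  bounds <- c(0, profile$switch_times, profile$horizon)
  out <- numeric(length(times))
  M_s <- M0
  for (seg in seq_along(profile$rates)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1L]
    m_inf <- profile$rates[seg] / delta_M
    in_seg <- times > t0 & times <= t1
    if (seg == 1L) in_seg <- in_seg | times == 0
    if (any(in_seg))
      out[in_seg] <- m_inf + (M_s - m_inf) * exp(-delta_M * (times[in_seg] - t0))
    M_s <- m_inf + (M_s - m_inf) * exp(-delta_M * (t1 - t0))
  }
  out
}

#' Closed-form protein path under piecewise-constant transcription
#'
#' Propagates the exact solution of the coupled system segment by segment.
#' Within a segment the mRNA path is exponential and the protein convolution
#' integral has the closed form
#' `P(u) = P_s e^{-dP u} + alpha m_inf (1 - e^{-dP u})/dP +
#'  alpha (M_s - m_inf) (e^{-dM u} - e^{-dP u})/(dP - dM)`,
#' with the removable `dP = dM` singularity handled by a series branch.
#'
#' @param P0,M0 Initial protein and mRNA levels.
#' @param profile A [switch_profile()].
#' @param delta_M,delta_P mRNA and protein decay rates (1/hour, positive).
#' @param alpha Translation rate.
#' @param times Evaluation grid within `[0, horizon]`.
#'
#' @return Numeric vector `P(times)`.
#' @export
protein_solution <- function(P0, M0, profile, delta_M, delta_P, times, alpha = 1) {
  stopifnot(inherits(profile, "switch_profile"))
  for (r in c(delta_M = delta_M, delta_P = delta_P))
    if (!is.finite(r) || r <= 0) stop("decay rates must be strictly positive")
  if (any(times < 0 | times > profile$horizon))
    stop("`times` must lie within [0, horizon]")

  bounds <- c(0, profile$switch_times, profile$horizon)
  out <- numeric(length(times))
  M_s <- M0; P_s <- P0
  for (seg in seq_along(profile$rates)) {
    t0 <- bounds[seg]; t1 <- bounds[seg + 1L]
    m_inf <- profile$rates[seg] / delta_M
    in_seg <- times > t0 & times <= t1
    if (seg == 1L) in_seg <- in_seg | times == 0
    seg_P <- function(u)
      P_s * exp(-delta_P * u) +
        alpha * m_inf * (-expm1(-delta_P * u)) / delta_P +
        alpha * (M_s - m_inf) * exp_diff_ratio(u, delta_M, delta_P)
    if (any(in_seg)) out[in_seg] <- seg_P(times[in_seg] - t0)
    P_s <- seg_P(t1 - t0)
    M_s <- m_inf + (M_s - m_inf) * exp(-delta_M * (t1 - t0))
  }
  out
}

#' Design matrix for the mRNA-mode linear model
#'
#' Columns of the linear regression representation of the mRNA solution:
#' `X_1 = e^{-delta_M t}`, `X_2 = 1 - e^{-delta_M t}` and, for each switch
#' `s_j`, `X_{j+2} = (1 - e^{-delta_M (t - s_j)})` for `t > s_j` and 0
#' otherwise (a switch cannot affect expression before it happens). The
#' coefficients are `beta_1 = M(0)`, `beta_2 = tau_0/delta_M`,
#' `beta_{j+2} = (tau_j - tau_{j-1})/delta_M`.
#'
#' @param times Observation times.
#' @param switch_times Sorted switch times inside the observation span (may
#'   be empty).
#' @param delta_M mRNA decay rate.
#'
#' @return Numeric matrix with `length(switch_times) + 2` columns.
#' @export
mrna_regressors <- function(times, switch_times, delta_M) {
  if (length(switch_times) > 1 && any(diff(switch_times) <= 0))
    stop("`switch_times` must be strictly increasing")
  e <- exp(-delta_M * times)
  X <- cbind(X1 = e, X2 = 1 - e)
  for (s in switch_times) {
    u <- pmax(times - s, 0)
    X <- cbind(X, ifelse(times > s, -expm1(-delta_M * u), 0))
  }
  colnames(X) <- paste0("X", seq_len(ncol(X)))
  X
}

#' Design matrix for the protein-mode linear model
#'
#' Columns of the linear regression representation of the protein solution:
#' `X_0 = e^{-delta_P t}`,
#' `X_1 = alpha (e^{-delta_M t} - e^{-delta_P t}) / (delta_P - delta_M)`, and
#' for `j >= 2` (with `s_0 = 0`, then one column per switch)
#' `X_j = alpha ((1 - e^{-delta_P u})/delta_P -
#'        (e^{-delta_M u} - e^{-delta_P u})/(delta_P - delta_M))`,
#' `u = t - s_{j-2}`, zero for `t <= s_{j-2}`. Coefficients are
#' `beta_0 = P(0)`, `beta_1 = M(0)`, `beta_2 = tau_0/delta_M`,
#' `beta_{j+2} = (tau_j - tau_{j-1})/delta_M`. The `delta_P = delta_M`
#' degeneracy is a removable singularity and is evaluated by a series branch,
#' so all entries are finite for any positive rate pair.
#'
#' @inheritParams mrna_regressors
#' @param delta_P Protein decay rate.
#' @param alpha Translation rate.
#'
#' @return Numeric matrix with `length(switch_times) + 3` columns.
#' @export
protein_regressors <- function(times, switch_times, delta_M, delta_P, alpha = 1) {
  if (length(switch_times) > 1 && any(diff(switch_times) <= 0))
    stop("`switch_times` must be strictly increasing")
  step_col <- function(s) {
    u <- pmax(times - s, 0)
    v <- alpha * ((-expm1(-delta_P * u)) / delta_P - exp_diff_ratio(u, delta_M, delta_P))
    ifelse(times > s, v, 0)
  }
  X <- cbind(X0 = exp(-delta_P * times),
             X1 = alpha * exp_diff_ratio(times, delta_M, delta_P),
             X2 = alpha * ((-expm1(-delta_P * times)) / delta_P -
                             exp_diff_ratio(times, delta_M, delta_P)))
  for (s in switch_times) X <- cbind(X, step_col(s))
  colnames(X) <- paste0("X", seq_len(ncol(X)) - 1L)
  X
}

#' Map regression coefficients to kinetic parameters
#'
#' Inverts the coefficient mapping of the linear model: in protein mode
#' `beta = (P0, M0, tau_0/delta_M, (tau_1 - tau_0)/delta_M, ...)`; mRNA mode
#' has no `P0` slot.
#'
#' @param betas Coefficient vector.
#' @param delta_M mRNA decay rate used to build the design matrix.
#' @param mode `"mRNA"` or `"protein"`.
#'
#' @return List with `P0` (`NA` in mRNA mode), `M0`, and `rates` (the
#'   transcription rates `tau_0 ... tau_k`).
#' @export
coefficients_to_params <- function(betas, delta_M, mode = c("mRNA", "protein")) {
  mode <- match.arg(mode)
  min_len <- if (mode == "protein") 3L else 2L
  if (length(betas) < min_len)
    stop("coefficient vector too short for ", mode, " mode")
  if (mode == "protein") {
    P0 <- betas[1]; M0 <- betas[2]; incr <- betas[-(1:2)]
  } else {
    P0 <- NA_real_; M0 <- betas[1]; incr <- betas[-1]
  }
  rates <- delta_M * cumsum(incr)
  list(P0 = P0, M0 = M0, rates = as.numeric(rates))
}

#' Map kinetic parameters to regression coefficients
#'
#' Forward companion of [coefficients_to_params()]; the round trip is the
#' identity.
#'
#' @param P0,M0 Initial conditions (`P0` ignored in mRNA mode).
#' @param rates Transcription rates `tau_0 ... tau_k`.
#' @inheritParams coefficients_to_params
#' @return Numeric coefficient vector matching the design-matrix columns.
#' @export
params_to_coefficients <- function(P0, M0, rates, delta_M, mode = c("mRNA", "protein")) {
  mode <- match.arg(mode)
  incr <- c(rates[1], diff(rates)) / delta_M
  if (mode == "protein") c(P0, M0, incr) else c(M0, incr)
}

#' Gamma shape/rate from mean and standard deviation
#'
#' Degradation-rate priors are supplied as (mean, sd) pairs; moment matching
#' gives `shape = mean^2/sd^2`, `rate = mean/sd^2`.
#'
#' @param mean,sd Strictly positive prior moments.
#' @return List with `shape` and `rate`.
#' @export
gamma_from_moments <- function(mean, sd) {
  if (length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("`mean` must be a single strictly positive number")
  if (length(sd) != 1L || !is.finite(sd) || sd <= 0)
    stop("`sd` must be a single strictly positive number")
  list(shape = mean^2 / sd^2, rate = mean / sd^2)
}
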