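# S3 containers shared by all modules.

#' Construct an expression time series
#'
#' Holds one observed time course (mRNA or protein-reporter expression) with
#' its replicate structure. Observation times are in hours and need not be
#' equidistant; values are in arbitrary expression units.
#'
#' @param name Series identifier (gene or reporter name).
#' @param times Numeric vector of observation times, or a list with one
#'   numeric vector per replicate.
#' @param values Numeric vector of observed expression, or a list parallel to
#'   `times`.
#' @param profile_type `"mRNA"` or `"protein"` -- which observation equation
#'   relates the data to the kinetic model.
#' @param annotations Character vector of extra annotation labels.
#' @param replicate_ids Optional replicate labels; defaults to `"r1"`,
#'   `"r2"`, ...
#'
#' @return An object of class `expression_series` with fields `name`,
#'   `annotations`, `times` (list per replicate), `values` (list per
#'   replicate), `replicate_ids` and `profile_type`.
#' @export
expression_series <- function(name, times, values,
                              profile_type = c("mRNA", "protein"),
                              annotations = character(),
                              replicate_ids = NULL) {
  profile_type <- match.arg(profile_type)
  if (!is.list(times)) times <- list(times)
  if (!is.list(values)) values <- list(values)
  if (length(times) != length(values))
    stop("`times` and `values` must have the same number of replicates")
  if (is.null(replicate_ids)) replicate_ids <- paste0("r", seq_along(times))

  for (r in seq_along(times)) {
    tt <- times[[r]]; yy <- values[[r]]
    keep <- is.finite(tt) & is.finite(yy)
    tt <- tt[keep]; yy <- yy[keep]
    if (length(tt) < 5L)
      stop("replicate '", replicate_ids[r], "' of series '", name,
           "' has fewer than 5 finite observations")
    if (any(diff(tt) <= 0))
      stop("observation times must be strictly increasing within replicate '",
           replicate_ids[r], "' of series '", name, "'")
    times[[r]] <- as.numeric(tt); values[[r]] <- as.numeric(yy)
  }

  structure(list(name = as.character(name),
                 annotations = as.character(annotations),
                 times = times, values = values,
                 replicate_ids = as.character(replicate_ids),
                 profile_type = profile_type),
            class = "expression_series")
}

#' @export
print.expression_series <- function(x, ...) {
  cat(sprintf("<expression_series> '%s' (%s), %d replicate(s), %s points, t in [%g, %g] h\n",
              x$name, x$profile_type, length(x$times),
              paste(vapply(x$times, length, 1L), collapse = "/"),
              min(unlist(x$times)), max(unlist(x$times))))
  invisible(x)
}

# Pooled (concatenated) observations of a series, ordered by time.
pool_series <- function(series) {
  tt <- unlist(series$times, use.names = FALSE)
  yy <- unlist(series$values, use.names = FALSE)
  rep_id <- rep(series$replicate_ids, vapply(series$times, length, 1L))
  o <- order(tt)
  list(times = tt[o], values = yy[o], replicate = rep_id[o])
}

#' Construct a piecewise-constant transcription profile
#'
#' A step transcription-rate function tau(t) on the interval `[0, horizon]`:
#' rate `rates[1]` up to `switch_times[1]`, `rates[2]` up to
#' `switch_times[2]`, and so on. The number of switches k may be zero.
#'
#' @param switch_times Strictly increasing switch times, all strictly inside
#'   `(0, horizon)` (hours).
#' @param rates k + 1 non-negative transcription rates (expression units per
#'   hour; scale-free when kappa * alpha = 1).
#' @param horizon Length L of the observed interval (hours).
#'
#' @return An object of class `switch_profile`.
#' @export
switch_profile <- function(switch_times, rates, horizon) {
  switch_times <- as.numeric(switch_times)
  rates <- as.numeric(rates)
  horizon <- as.numeric(horizon)
  if (length(horizon) != 1L || !is.finite(horizon) || horizon <= 0)
    stop("`horizon` must be a single positive number")
  k <- length(switch_times)
  if (length(rates) != k + 1L)
    stop("need exactly one more rate than switch times (got ", length(rates),
         " rates for k = ", k, ")")
  if (k > 0) {
    if (any(diff(switch_times) <= 0)) stop("switch times must be strictly increasing")
    if (any(switch_times <= 0 | switch_times >= horizon))
      stop("switch times must lie strictly inside (0, horizon)")
  }
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("transcription rates must be finite and non-negative")
  structure(list(switch_times = switch_times, rates = rates, horizon = horizon),
            class = "switch_profile")
}

#' @export
print.switch_profile <- function(x, ...) {
  cat(sprintf("<switch_profile> k = %d on [0, %g] h\n", length(x$switch_times), x$horizon))
  if (length(x$switch_times))
    cat("  switches at:", paste(signif(x$switch_times, 4), collapse = ", "), "h\n")
  cat("  rates:", paste(signif(x$rates, 4), collapse = ", "), "\n")
  invisible(x)
}

# Evaluate tau(t) of a switch_profile at arbitrary times.
eval_switch_profile <- function(profile, times) {
  idx <- findInterval(times, profile$switch_times, left.open = TRUE) + 1L
  profile$rates[idx]
}

#' Construct kinetic priors and fixed scalings
#'
#' Gamma-prior moments for the mRNA decay rate delta_M (and, for
#' protein-reporter data, the protein decay rate delta_P), together with the
#' fixed translation rate alpha and measurement scaling kappa. Only the
#' product kappa * alpha is identifiable from expression data, so both
#' default to 1 and reconstructions are on an arbitrary but consistent scale.
#'
#' @param delta_M_mean,delta_M_sd Prior mean and standard deviation of the
#'   mRNA decay rate (1/hour).
#' @param delta_P_mean,delta_P_sd Prior moments of the protein decay rate
#'   (1/hour); may be `NULL` for mRNA-only analyses.
#' @param alpha Translation rate (fixed).
#' @param kappa Measurement proportionality constant (fixed).
#'
#' @return An object of class `kinetic_priors`.
#' @export
kinetic_priors <- function(delta_M_mean, delta_M_sd,
                           delta_P_mean = NULL, delta_P_sd = NULL,
                           alpha = 1, kappa = 1) {
  chk <- function(x, nm) {
    if (length(x) != 1L || !is.finite(x) || x <= 0)
      stop("`", nm, "` must be a single strictly positive number")
    as.numeric(x)
  }
  out <- list(delta_M_mean = chk(delta_M_mean, "delta_M_mean"),
              delta_M_sd = chk(delta_M_sd, "delta_M_sd"),
              delta_P_mean = if (!is.null(delta_P_mean)) chk(delta_P_mean, "delta_P_mean"),
              delta_P_sd = if (!is.null(delta_P_sd)) chk(delta_P_sd, "delta_P_sd"),
              alpha = chk(alpha, "alpha"), kappa = chk(kappa, "kappa"))
  if (is.null(out$delta_P_mean) != is.null(out$delta_P_sd))
    stop("provide both or neither of `delta_P_mean` and `delta_P_sd`")
  structure(out, class = "kinetic_priors")
}

#' @export
print.kinetic_priors <- function(x, ...) {
  cat(sprintf("<kinetic_priors> delta_M ~ Gamma(mean %g, sd %g)\n",
              x$delta_M_mean, x$delta_M_sd))
  if (!is.null(x$delta_P_mean))
    cat(sprintf("  delta_P ~ Gamma(mean %g, sd %g)\n", x$delta_P_mean, x$delta_P_sd))
  cat(sprintf("  alpha = %g, kappa = %g\n", x$alpha, x$kappa))
  invisible(x)
}
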