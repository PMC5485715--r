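# Posterior summarisation of switch-model chains: baseline-removed
# switch-time density, Gaussian-mixture event calls, per-model-size
# densities and univariate parameter percentiles.

#' Summarise the switch-time posterior of a chain
#'
#' Pools all post-burn-in sampled switch times, forms a kernel-density
#' estimate on `[0, L]`, removes a uniform baseline (the density that
#' diffusely scattered switches would produce, at level `mean(k)/L`) and
#' clips at zero. Switch events are then called by fitting a Gaussian
#' mixture with as many components as the posterior modal `k`; each
#' component reports a mean, standard deviation, weight (scaled so that the
#' baseline mass is excluded) and a direction -- increase or decrease --
#' taken from the sign of the average transcription-rate increment of the
#' samples assigned to it. Densities conditional on each sampled model size
#' are also returned, ordered by sampled frequency.
#'
#' @param chains A [run_switch()] result.
#' @param grid_n Number of density evaluation points (default 512).
#'
#' @return An object of class `switch_summary`: `model_size_histogram`,
#'   `modal_k`, `switch_density` (data frame `time`, `density`,
#'   `density_raw`), `baseline`, `mixture` (data frame `mean`, `sd`,
#'   `weight`, `direction`), `per_model_size` (named list of densities) and
#'   `parameters` (from [summarize_parameters()]).
#' @export
summarize_switches <- function(chains, grid_n = 512L) {
  stopifnot(inherits(chains, "switch_chains"))
  keep <- seq_along(chains$k) > chains$burn_in
  k_post <- chains$k[keep]
  s_post <- chains$s[keep]
  b_post <- chains$betas[keep]
  dM_post <- chains$delta_M[keep]
  L0 <- chains$time_offset
  L1 <- chains$time_offset + chains$horizon

  hist_k <- table(factor(k_post, levels = 0:chains$kmax))
  modal_k <- as.integer(names(hist_k)[which.max(hist_k)])

  pooled <- unlist(s_post, use.names = FALSE)
  grid <- seq(L0, L1, length.out = grid_n)
  baseline <- mean(k_post) / chains$horizon

  empty <- list(time = grid, density = rep(0, grid_n), density_raw = rep(0, grid_n))
  if (length(pooled) == 0) {
    sw_dens <- as.data.frame(empty)
  } else {
    kd <- stats::density(pooled, from = L0, to = L1, n = grid_n)
    # density() integrates to 1; scale to expected switch count so the
    # uniform baseline mean(k)/L is on the same scale
    raw <- kd$y * mean(k_post)
    sw_dens <- data.frame(time = grid, density = pmax(raw - baseline, 0),
                          density_raw = raw)
  }

  mixture <- data.frame(mean = numeric(0), sd = numeric(0),
                        weight = numeric(0), direction = character(0))
  if (modal_k > 0 && length(pooled) >= max(10, 2 * modal_k)) {
    # baseline scatter is handled as mclust's uniform noise component,
    # initialised from the samples falling below the baseline density
    noise_init <- stats::approx(sw_dens$time, sw_dens$density_raw,
                                pooled, rule = 2)$y <= baseline
    if (all(noise_init)) noise_init[] <- FALSE
    fit <- tryCatch(
      mclust::Mclust(pooled, G = modal_k, modelNames = "V",
                     initialization = if (any(noise_init)) list(noise = noise_init),
                     verbose = FALSE),
      error = function(e) NULL)
    if (is.null(fit) || is.null(fit$parameters))
      fit <- tryCatch(
        mclust::Mclust(pooled, G = modal_k, modelNames = "V", verbose = FALSE),
        error = function(e) NULL)
    if (!is.null(fit) && !is.null(fit$parameters)) {
      mu <- as.numeric(fit$parameters$mean)
      sdv <- sqrt(as.numeric(fit$parameters$variance$sigmasq))
      if (length(sdv) == 1L) sdv <- rep(sdv, length(mu))
      wts <- as.numeric(fit$parameters$pro)[seq_along(mu)]  # drop noise entry
      cls <- fit$classification
      # direction: sign of the mean rate increment of samples in the component
      incr <- unlist(mapply(function(s, b, dM) {
        if (length(s) == 0) return(numeric(0))
        pars <- coefficients_to_params(b, dM, chains$mode)
        diff(pars$rates)   # rate increment at switch j: tau_j - tau_{j-1}
      }, s_post, b_post, dM_post, SIMPLIFY = FALSE), use.names = FALSE)
      dir <- vapply(seq_along(mu), function(j) {
        m <- incr[cls == j]
        if (length(m) == 0 || mean(m) >= 0) "increase" else "decrease"
      }, character(1))
      o <- order(mu)
      mixture <- data.frame(mean = mu[o], sd = sdv[o], weight = wts[o],
                            direction = dir[o], stringsAsFactors = FALSE)
    }
  }

  sizes <- sort(table(k_post[k_post > 0]), decreasing = TRUE)
  per_model_size <- list()
  if (length(sizes) > 0) {
    per_model_size <- lapply(names(sizes), function(kk) {
      ss <- unlist(s_post[k_post == as.integer(kk)], use.names = FALSE)
      kd <- stats::density(ss, from = L0, to = L1, n = grid_n)
      data.frame(time = kd$x, density = kd$y * as.integer(kk))
    })
    names(per_model_size) <- paste0("k=", names(sizes))
  }

  structure(list(model_size_histogram = hist_k, modal_k = modal_k,
                 switch_density = sw_dens, baseline = baseline,
                 mixture = mixture, per_model_size = per_model_size,
                 parameters = summarize_parameters(chains)),
            class = "switch_summary")
}

#' Percentile summaries of the univariate parameter chains
#'
#' Median, lower/upper quartiles, mean and mean +/- 1.96 sd for the noise
#' variance and the decay rates, over post-burn-in samples.
#'
#' @param chains A [run_switch()] result.
#' @return Data frame with one row per parameter (`sigma2`, `delta_M` and,
#'   in protein mode, `delta_P`).
#' @export
summarize_parameters <- function(chains) {
  stopifnot(inherits(chains, "switch_chains"))
  keep <- seq_along(chains$k) > chains$burn_in
  one <- function(x) {
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    m <- mean(x); s <- stats::sd(x)
    data.frame(median = q[2], q25 = q[1], q75 = q[3], mean = m, sd = s,
               lower95 = m - 1.96 * s, upper95 = m + 1.96 * s)
  }
  pars <- list(sigma2 = chains$sigma2[keep], delta_M = chains$delta_M[keep])
  if (chains$mode == "protein") pars$delta_P <- chains$delta_P[keep]
  out <- do.call(rbind, lapply(pars, one))
  out$parameter <- names(pars)
  rownames(out) <- NULL
  out[, c("parameter", "median", "q25", "q75", "mean", "sd", "lower95", "upper95")]
}

#' @export
print.switch_summary <- function(x, ...) {
  cat(sprintf("<switch_summary> modal k = %d; baseline density %.4g\n",
              x$modal_k, x$baseline))
  if (nrow(x$mixture)) {
    cat("  switch events (Gaussian mixture):\n")
    for (i in seq_len(nrow(x$mixture)))
      cat(sprintf("    %s at %.2f h (sd %.2f, weight %.2f)\n",
                  x$mixture$direction[i], x$mixture$mean[i],
                  x$mixture$sd[i], x$mixture$weight[i]))
  } else cat("  no switch events called\n")
  invisible(x)
}

#' Write switch chains and summary to CSV + JSON
#'
#' @param chains A [run_switch()] result.
#' @param summary Optional [summarize_switches()] result (computed if
#'   missing).
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_switch_result <- function(chains, summary = NULL, dir) {
  if (is.null(summary)) summary <- summarize_switches(chains)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", chains$name), "_switch"))
  df <- data.frame(
    iteration = seq_along(chains$k) * chains$thin,
    k = chains$k,
    s = vapply(chains$s, function(v) paste(signif(v, 8), collapse = ";"), character(1)),
    beta = vapply(chains$betas, function(v) paste(signif(v, 8), collapse = ";"), character(1)),
    delta_M = chains$delta_M, delta_P = chains$delta_P, sigma2 = chains$sigma2,
    move = chains$move, accepted = chains$accepted)
  csv <- paste0(stem, "_chains.csv")
  utils::write.csv(df, csv, row.names = FALSE)
  js <- paste0(stem, "_summary.json")
  jsonlite::write_json(list(
    series = chains$name, mode = chains$mode, seed = chains$seed,
    iterations = chains$iterations, thin = chains$thin,
    burn_in_stored = chains$burn_in, kmax = chains$kmax,
    regression = chains$regression,
    modal_k = summary$modal_k,
    model_size_histogram = as.list(stats::setNames(
      as.integer(summary$model_size_histogram),
      names(summary$model_size_histogram))),
    mixture = summary$mixture,
    parameters = summary$parameters
  ), js, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(chains = csv, summary = js))
}
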