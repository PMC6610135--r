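#' Spike-triggered median membrane potential
#'
#' The pointwise median of Vm snippets aligned to the spikes of a putative
#' presynaptic unit. The median (rather than the mean) is robust to the
#' skew that residual action potentials introduce into the Vm
#' distribution. Snippets whose window falls outside the trace are
#' dropped; at least 10 usable spikes are required.
#'
#' @param vm Membrane-potential trace, mV.
#' @param fs Sampling rate, Hz.
#' @param spike_times Presynaptic spike times, s.
#' @param window Snippet window around each spike `c(pre, post)`, s
#'   (pre is negative).
#' @param t0 Time of the first Vm sample, s.
#' @return A list: `lag` (s), `median_trace` (mV), `n_used`.
#' @export
spike_triggered_median <- function(vm, fs, spike_times,
                                   window = c(-0.02, 0.08), t0 = 0) {
  snip <- stm_snippets(vm, fs, spike_times, window, t0)
  list(lag = snip$lag, median_trace = apply(snip$mat, 2, median),
       n_used = nrow(snip$mat))
}

stm_snippets <- function(vm, fs, spike_times, window, t0) {
  pre <- as.integer(round(window[1] * fs))
  post <- as.integer(round(window[2] * fs))
  centers <- as.integer(round((spike_times - t0) * fs)) + 1L
  ok <- centers + pre >= 1L & centers + post <= length(vm)
  centers <- centers[ok]
  if (length(centers) < 10) {
    abort(sprintf("Need at least 10 spikes with full windows; got %d.",
                  length(centers)))
  }
  offs <- pre:post
  idx <- outer(centers, offs, `+`)
  list(mat = matrix(vm[idx], nrow = length(centers)), lag = offs / fs)
}

#' Z-score a trace against baseline statistics
#'
#' `(x - mu) / sigma`, with `mu` and `sigma` normally taken from the whole
#' recording so that spike-triggered traces from cells with different
#' levels of synaptic fluctuation are comparable.
#'
#' @param x Numeric vector.
#' @param mu,sigma Baseline mean and standard deviation; default to the
#'   moments of `x` itself.
#' @return Z-scored vector.
#' @export
zscore_trace <- function(x, mu = mean(x), sigma = sd(x)) {
  if (!is.finite(sigma) || sigma <= 0) {
    abort("Degenerate baseline: sigma must be positive.")
  }
  (x - mu) / sigma
}

#' Interval-jitter surrogate spike trains
#'
#' The time axis is partitioned into consecutive fixed bins (default
#' 100 ms, anchored at `t0`) and each spike is redrawn uniformly within
#' its bin. Per-bin spike counts -- and hence the rate profile at the bin
#' resolution -- are preserved exactly, while temporal structure finer
#' than the bin is destroyed.
#'
#' @param spike_times Spike times, s.
#' @param interval Jitter bin width, s.
#' @param t0 Partition anchor, s.
#' @param seed Optional integer seed.
#' @return Jittered spike times (sorted), same length as the input.
#' @export
interval_jitter <- function(spike_times, interval = 0.1, t0 = 0, seed = NULL) {
  check_scalar_number(interval, "interval", min = 1e-12)
  set_seed_if(seed)
  bins <- floor((spike_times - t0) / interval)
  sort(t0 + (bins + runif(length(spike_times))) * interval)
}

#' Assess a putative connection by spike-triggered median
#'
#' Computes the z-scored spike-triggered median Vm for one presynaptic
#' unit, builds `n_jitters` surrogate medians from interval-jittered spike
#' times, and tests whether the observed extremum in the causal synaptic
#' window stands outside the surrogate peak distribution. The peak is the
#' largest absolute deviation from the pointwise surrogate mean (in
#' pointwise surrogate-sigma units) over lags 0.5-30 ms; it is significant
#' when it exceeds the surrogate peaks' mean by more than two of their
#' standard deviations (the +/-2 sigma criterion applied to the jittered
#' peak distribution). For a significant negative (inhibitory) peak the
#' IPSP decay constant is fitted with [fit_ipsp_decay()].
#'
#' @inheritParams spike_triggered_median
#' @param n_jitters Number of surrogate spike trains (>= 50).
#' @param jitter_interval Jitter bin width, s.
#' @param search_window Causal lag window searched for the peak, s.
#' @param seed Optional integer seed.
#' @param fit_decay If `TRUE`, fit the IPSP decay when significant/negative.
#' @return A `cpg_stm` list: `n`, `lag`, `z` (observed z-scored median),
#'   `null_mean`, `null_sd` (pointwise surrogate traces), `peak_z`
#'   (observed peak in pointwise sigma units), `null_peaks`, `polarity`,
#'   `significant`, `tau_ms` (or `NA`).
#' @examples
#' \donttest{
#' cp <- make_connected_pair(psp_amplitude = -0.5, n_spikes = 600, seed = 1)
#' res <- assess_connection(cp$vm, cp$fs, cp$spike_times, n_jitters = 50,
#'                          seed = 2)
#' glance(res)
#' }
#' @export
assess_connection <- function(vm, fs, spike_times, window = c(-0.02, 0.08),
                              n_jitters = 100, jitter_interval = 0.1,
                              search_window = c(5e-4, 0.03), seed = NULL,
                              t0 = 0, fit_decay = TRUE) {
  if (n_jitters < 50) abort("`n_jitters` must be at least 50.")
  mu <- mean(vm)
  sigma <- sd(vm)
  obs <- spike_triggered_median(vm, fs, spike_times, window, t0)
  z_obs <- zscore_trace(obs$median_trace, mu, sigma)

  set_seed_if(seed)
  z_null <- vapply(seq_len(n_jitters), function(j) {
    st <- interval_jitter(spike_times, jitter_interval, t0 = t0)
    zscore_trace(
      spike_triggered_median(vm, fs, st, window, t0)$median_trace, mu, sigma)
  }, numeric(length(z_obs)))

  null_mean <- rowMeans(z_null)
  null_sd <- apply(z_null, 1, sd)
  null_sd[null_sd == 0] <- NA_real_

  in_win <- obs$lag >= search_window[1] & obs$lag <= search_window[2]
  dev_obs <- (z_obs - null_mean) / null_sd
  peak_i <- which(in_win)[which.max(abs(dev_obs[in_win]))]
  peak_z <- dev_obs[peak_i]

  null_peaks <- apply(z_null, 2, function(z) {
    d <- (z - null_mean) / null_sd
    max(abs(d[in_win]), na.rm = TRUE)
  })
  significant <- abs(peak_z) > mean(null_peaks) + 2 * sd(null_peaks)
  polarity <- if (peak_z < 0) "inhibitory" else "excitatory"

  tau_ms <- NA_real_
  fit <- NULL
  if (significant && peak_z < 0 && fit_decay) {
    fit <- try(fit_ipsp_decay(z_obs, fs, obs$lag, trough_lag = obs$lag[peak_i]),
               silent = TRUE)
    if (!inherits(fit, "try-error")) tau_ms <- fit$tau_ms else fit <- NULL
  }
  structure(
    list(n = obs$n_used, lag = obs$lag, z = z_obs, null_mean = null_mean,
         null_sd = null_sd, peak_lag = obs$lag[peak_i], peak_z = peak_z,
         null_peaks = null_peaks, polarity = polarity,
         significant = significant, tau_ms = tau_ms, fit = fit,
         window = window, search_window = search_window),
    class = "cpg_stm")
}

#' @export
print.cpg_stm <- function(x, ...) {
  cat(sprintf("<cpg_stm> N = %d spikes; peak %.2f sigma at %.1f ms (%s); %s%s\n",
              x$n, x$peak_z, x$peak_lag * 1000, x$polarity,
              if (x$significant) "significant" else "not significant",
              if (is.finite(x$tau_ms)) sprintf("; tau = %.1f ms", x$tau_ms) else ""))
  invisible(x)
}

#' @rdname assess_connection
#' @param x A `cpg_stm` object.
#' @param ... Unused.
#' @export
tidy.cpg_stm <- function(x, ...) {
  tibble(lag = x$lag, z = x$z, null_mean = x$null_mean, null_sd = x$null_sd)
}

#' @rdname assess_connection
#' @export
glance.cpg_stm <- function(x, ...) {
  tibble(n = x$n, peak_z = x$peak_z, peak_lag_ms = x$peak_lag * 1000,
         polarity = x$polarity, significant = x$significant,
         tau_ms = x$tau_ms)
}

#' Fit the decay constant of an IPSP
#'
#' Least-squares single-exponential fit of the recovery from the trough
#' toward baseline, over a fixed span after the trough (default 25 ms):
#' `z(t) = A exp(-(t - t_trough) / tau) + b`. The baseline `b` is anchored
#' to the pre-spike mean of the trace (a free baseline over a short span
#' is ill-conditioned and biases tau). A glycinergic IPSP decays with tau
#' around 5 ms; GABAergic inhibition is several-fold slower.
#'
#' @param z Z-scored spike-triggered median trace.
#' @param fs Sampling rate, Hz.
#' @param lag Lag axis of `z`, s.
#' @param trough_lag Lag of the trough, s; located automatically within
#'   3-30 ms when missing.
#' @param span Fit span after the trough, s.
#' @param baseline Baseline level; defaults to the mean of `z` at negative
#'   lags (or 0 if there are none).
#' @return A list: `tau_ms`, `amplitude`, `baseline`, `residual_rms`,
#'   `poor_fit` flag (with a warning when the recovery is badly
#'   non-exponential).
#' @export
fit_ipsp_decay <- function(z, fs, lag = (seq_along(z) - 1) / fs,
                           trough_lag = NULL, span = 0.025,
                           baseline = NULL) {
  if (is.null(trough_lag)) {
    cand <- which(lag >= 0.003 & lag <= 0.03)
    trough_lag <- lag[cand[which.min(z[cand])]]
  }
  if (is.null(baseline)) {
    baseline <- if (any(lag < 0)) mean(z[lag < 0]) else 0
  }
  sel <- which(lag >= trough_lag & lag <= trough_lag + span)
  if (length(sel) < 5) abort("Too few samples after the trough to fit a decay.")
  tt <- (lag[sel] - trough_lag) * 1000 # ms
  zz <- z[sel] - baseline
  fit <- minpack.lm::nlsLM(
    zz ~ a * exp(-tt / tau),
    start = list(a = zz[1], tau = 5),
    lower = c(a = -Inf, tau = 0.1),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  res_rms <- sqrt(mean(stats::resid(fit)^2))
  poor <- res_rms > 0.5 * abs(cf[["a"]])
  if (poor) {
    warn(sprintf("IPSP decay fit is poor (residual RMS %.3g vs amplitude %.3g).",
                 res_rms, abs(cf[["a"]])))
  }
  list(tau_ms = cf[["tau"]], amplitude = cf[["a"]], baseline = baseline,
       residual_rms = res_rms, poor_fit = poor)
}

#' Probe connections from many units onto one cell
#'
#' Runs [assess_connection()] for every unit of a `spike_trains` set
#' against a single intracellular trace and tabulates the results; the
#' connection probability is the fraction of tested units with a
#' significant peak.
#'
#' @inheritParams assess_connection
#' @param spikes A `spike_trains` tibble.
#' @param min_spikes Units with fewer spikes are skipped.
#' @return Tibble with one row per tested unit: `unit`, `n`, `peak_z`,
#'   `peak_lag_ms`, `polarity`, `significant`, `tau_ms`; the connection
#'   probability is attached as attribute `connection_probability`.
#' @export
probe_connections <- function(vm, fs, spikes, window = c(-0.02, 0.08),
                              n_jitters = 100, jitter_interval = 0.1,
                              search_window = c(5e-4, 0.03), seed = NULL,
                              t0 = 0, min_spikes = 10) {
  units <- attr(spikes, "units")
  if (is.null(units)) units <- sort(unique(spikes$unit))
  rows <- purrr::imap(units, function(u, i) {
    tt <- spikes$time[spikes$unit == u]
    if (length(tt) < min_spikes) {
      return(tibble(unit = u, n = length(tt), peak_z = NA_real_,
                    peak_lag_ms = NA_real_, polarity = NA_character_,
                    significant = NA, tau_ms = NA_real_))
    }
    res <- assess_connection(vm, fs, tt, window, n_jitters, jitter_interval,
                             search_window,
                             seed = if (is.null(seed)) NULL
                                    else derive_seed(seed, i),
                             t0 = t0)
    dplyr::mutate(glance(res), unit = u, .before = 1)
  })
  out <- dplyr::bind_rows(rows)
  tested <- !is.na(out$significant)
  attr(out, "connection_probability") <-
    if (any(tested)) mean(out$significant[tested]) else NA_real_
  out
}
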