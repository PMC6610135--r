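#' Gaussian-kernel firing-rate estimate
#'
#' Convolves the spike train with a unit-area Gaussian kernel
#' `k(t) = exp(-t^2 / (2 sigma^2)) / (sqrt(2 pi) sigma)`, sampled on a
#' regular grid. The narrow kernel (`sigma` = 5 ms) captures fast synaptic
#' timing; the broad one (`sigma` = 150 ms) captures the slow rate
#' modulation. The kernel is truncated at five sigma; an empty train gives
#' a zero trace.
#'
#' @param times Spike times, s.
#' @param sigma Kernel width, s.
#' @param fs Sampling rate of the rate trace, Hz.
#' @param interval Recording interval `c(t0, t1)`, s.
#' @return A tibble with columns `time`, `rate` (spikes/s).
#' @examples
#' kr <- kernel_rate(c(0.5, 0.52, 1.4), sigma = 0.15, fs = 1000,
#'                   interval = c(0, 2))
#' @export
kernel_rate <- function(times, sigma, fs = 1000, interval) {
  check_scalar_number(sigma, "sigma", min = 1e-9)
  if (fs <= 1 / sigma) abort("`fs` must exceed 1/sigma to resolve the kernel.")
  grid <- seq(interval[1], interval[2], by = 1 / fs)
  rate <- rate_on_grid(times, sigma, fs, grid)
  tibble(time = grid, rate = rate)
}

rate_on_grid <- function(times, sigma, fs, grid) {
  n <- length(grid)
  if (!length(times)) return(numeric(n))
  counts <- numeric(n)
  idx <- as.integer(round((times - grid[1]) * fs)) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  tab <- tabulate(idx, nbins = n)
  half <- as.integer(ceiling(5 * sigma * fs))
  kern <- dnorm(seq(-half, half) / fs, sd = sigma)
  full <- stats::convolve(tab, rev(kern), type = "open")
  full[(half + 1L):(half + n)]
}

#' Slow and fast spike-rate correlation matrices
#'
#' Implements the two-timescale decomposition for population spiking: each
#' unit's spike train is convolved with a broad (`sigma` = 150 ms) and a
#' narrow (`sigma` = 5 ms) Gaussian kernel, the resulting rate traces are
#' high-pass filtered (3-pole zero-phase Butterworth) at 0.3 Hz (slow) and
#' 10 Hz (fast), and Pearson correlations are assembled into two symmetric
#' unit-diagonal matrices. Units with zero spikes are excluded (reported in
#' the `excluded` attribute and a warning).
#'
#' @param spikes A `spike_trains` tibble (columns `unit`, `time`).
#' @param fs Rate-trace sampling rate, Hz.
#' @param interval Analysis interval; defaults to the recording interval.
#' @param sigma_slow,sigma_fast Kernel widths, s.
#' @param hp_slow,hp_fast High-pass cutoffs, Hz.
#' @return A list with matrices `slow` and `fast` (dimnames = unit ids) and
#'   `excluded` (unit ids with no spikes).
#' @export
rate_correlation_matrices <- function(spikes, fs = 1000, interval = NULL,
                                      sigma_slow = 0.15, sigma_fast = 0.005,
                                      hp_slow = 0.3, hp_fast = 10) {
  if (is.null(interval)) interval <- attr(spikes, "interval")
  if (is.null(interval)) interval <- range(spikes$time)
  units <- attr(spikes, "units")
  if (is.null(units)) units <- sort(unique(spikes$unit))
  if (length(units) < 2) abort("Need at least 2 units.")
  by_unit <- split(spikes$time, factor(spikes$unit, levels = units))
  counts <- lengths(by_unit)
  excluded <- units[counts == 0]
  if (length(excluded)) {
    warn(sprintf("Excluding %d unit(s) with zero spikes: %s",
                 length(excluded), paste(excluded, collapse = ", ")))
  }
  keep <- units[counts > 0]
  grid <- seq(interval[1], interval[2], by = 1 / fs)
  band <- function(sigma, cutoff) {
    m <- vapply(by_unit[as.character(keep)], function(tt) {
      butter_filtfilt(rate_on_grid(tt, sigma, fs, grid), fs, cutoff, "high")
    }, numeric(length(grid)))
    r <- cor(m)
    dimnames(r) <- list(keep, keep)
    r
  }
  list(slow = band(sigma_slow, hp_slow), fast = band(sigma_fast, hp_fast),
       excluded = excluded)
}

#' Rayleigh test for circular uniformity of spike phases
#'
#' The mean resultant length `R` of the spike phases gives the test
#' statistic `z = N R^2`; the p-value uses the standard approximation
#' `p = exp(sqrt(1 + 4N + 4(N^2 - R_N^2)) - (1 + 2N))` with `R_N = N R`.
#' Units whose spiking is not phase-locked to the motor rhythm fail the
#' test and are excluded from population correlation analyses.
#'
#' @param phases Spike phases, radians.
#' @param alpha Significance level.
#' @return One-row tibble: `n`, `r` (mean resultant length), `r_n`, `z`,
#'   `p_value`, `preferred_phase_deg` (circular mean direction),
#'   `significant`.
#' @examples
#' rayleigh_test(rep(pi / 3, 10))
#' @export
rayleigh_test <- function(phases, alpha = 0.05) {
  n <- length(phases)
  if (n < 1) abort("Rayleigh test needs at least one spike phase.")
  cbar <- mean(cos(phases))
  sbar <- mean(sin(phases))
  r <- sqrt(cbar^2 + sbar^2)
  rn <- r * n
  z <- n * r^2
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - rn^2)) - (1 + 2 * n))
  p <- min(1, p)
  tibble(n = n, r = r, r_n = rn, z = z, p_value = p,
         preferred_phase_deg = wrap_degrees(atan2(sbar, cbar) * 180 / pi),
         significant = p < alpha)
}

#' Instantaneous phase of a reference rhythm
#'
#' Smooths the reference (nerve) trace with a Gaussian kernel
#' (`sigma` = 150 ms), removes the offset with a 0.1 Hz high-pass, and
#' takes the angle of the analytic signal (Hilbert transform). Phase is
#' only defined during ongoing activity: masked-out samples are `NA`.
#'
#' @param x Reference trace.
#' @param fs Sampling rate, Hz.
#' @param mask Optional logical vector, `TRUE` where activity is ongoing.
#' @param highpass High-pass cutoff, Hz.
#' @param smooth_sigma Gaussian smoothing width, s (0 disables).
#' @return Phase trace in radians `(-pi, pi]`, `NA` outside activity.
#' @export
instantaneous_phase <- function(x, fs, mask = NULL, highpass = 0.1,
                                smooth_sigma = 0.15) {
  if (!is.null(mask) && !any(mask)) abort("All samples are masked out; phase undefined.")
  if (smooth_sigma > 0) {
    half <- as.integer(ceiling(5 * smooth_sigma * fs))
    kern <- dnorm(seq(-half, half) / fs, sd = smooth_sigma)
    kern <- kern / sum(kern)
    padded <- reflect_pad(x, half)
    sm <- stats::convolve(padded$x, rev(kern), type = "open")
    x <- sm[(half + padded$p + 1L):(half + padded$p + length(x))]
  }
  x <- butter_filtfilt(x, fs, highpass, type = "high")
  ph <- Arg(analytic_signal(x))
  if (!is.null(mask)) ph[!mask] <- NA_real_
  ph
}

#' Spike-triggered phase histogram
#'
#' Histogram of the reference-rhythm phase at each spike time, with the
#' preferred phase estimated as the circular mean direction (the estimator
#' underlying the Rayleigh resultant).
#'
#' @param spike_times Spike times, s.
#' @param phase Phase trace (radians) at rate `fs`; `NA` where undefined.
#' @param fs Sampling rate of `phase`, Hz.
#' @param t0 Time of the first phase sample, s.
#' @param n_bins Number of histogram bins over `[0, 360)` degrees.
#' @return A `phase_hist` list: `breaks_deg`, `counts`,
#'   `preferred_phase_deg`, `r`, `n`, `spike_phases` (radians).
#' @export
spike_triggered_phase_hist <- function(spike_times, phase, fs, t0 = 0,
                                       n_bins = 18) {
  idx <- as.integer(round((spike_times - t0) * fs)) + 1L
  idx <- idx[idx >= 1L & idx <= length(phase)]
  ph <- phase[idx]
  ph <- ph[!is.na(ph)]
  if (!length(ph)) abort("No spikes fall in epochs with defined phase.")
  deg <- wrap_degrees(ph * 180 / pi)
  breaks <- seq(0, 360, length.out = n_bins + 1)
  counts <- hist(deg, breaks = breaks, plot = FALSE)$counts
  rt <- rayleigh_test(ph)
  structure(list(breaks_deg = breaks, counts = counts,
                 preferred_phase_deg = rt$preferred_phase_deg, r = rt$r,
                 n = length(ph), spike_phases = ph),
            class = "phase_hist")
}

#' @importFrom graphics hist
NULL

#' Screen units for rhythmicity
#'
#' Applies the Rayleigh test to each unit's spike phases and reports which
#' units are significantly phase-locked to the reference rhythm. Units
#' without rhythmic activity (or without spikes in active epochs) are
#' excluded from downstream matrix analyses.
#'
#' @param spikes A `spike_trains` tibble.
#' @param phase Phase trace (radians) at rate `fs`.
#' @param fs Sampling rate of `phase`, Hz.
#' @param t0 Time of the first phase sample, s.
#' @param alpha Per-unit significance level.
#' @param bonferroni If `TRUE`, divide `alpha` by the number of units.
#' @return Tibble with one row per unit: `unit`, `n`, `r`, `z`, `p_value`,
#'   `preferred_phase_deg`, `included`, `reason`.
#' @export
screen_rhythmic_units <- function(spikes, phase, fs, t0 = 0, alpha = 0.05,
                                  bonferroni = FALSE) {
  units <- attr(spikes, "units")
  if (is.null(units)) units <- sort(unique(spikes$unit))
  a <- if (bonferroni) alpha / length(units) else alpha
  rows <- purrr::map(units, function(u) {
    tt <- spikes$time[spikes$unit == u]
    idx <- as.integer(round((tt - t0) * fs)) + 1L
    idx <- idx[idx >= 1L & idx <= length(phase)]
    ph <- phase[idx]
    ph <- ph[!is.na(ph)]
    if (!length(ph)) {
      return(tibble(unit = u, n = 0L, r = NA_real_, z = NA_real_,
                    p_value = NA_real_, preferred_phase_deg = NA_real_,
                    included = FALSE, reason = "no spikes"))
    }
    rt <- rayleigh_test(ph, alpha = a)
    tibble(unit = u, n = rt$n, r = rt$r, z = rt$z, p_value = rt$p_value,
           preferred_phase_deg = rt$preferred_phase_deg,
           included = rt$significant,
           reason = if (rt$significant) "rhythmic" else "not rhythmic")
  })
  dplyr::bind_rows(rows)
}
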