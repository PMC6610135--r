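#' Split a membrane potential into slow and fast components
#'
#' The slow component (rate modulation) is the 0.2-5 Hz band; the fast
#' component (synaptic fluctuations) is everything above 5 Hz. Both use a
#' 3-pole Butterworth applied forward and backward (zero phase), with odd
#' reflection padding of about three filter time constants at the edges.
#' An optional pre-pass clips residual action potentials (samples beyond
#' `spike_clip_sd` standard deviations above the mean) and linearly
#' interpolates across them.
#'
#' @param x Numeric vector (mV), a matrix with one column per cell, or a
#'   `vm_traces` object.
#' @param fs Sampling rate, Hz. Taken from `x` for `vm_traces`.
#' @param slow_band Slow band-pass edges, Hz.
#' @param fast_cutoff Fast high-pass cutoff, Hz.
#' @param order Butterworth order.
#' @param clip_spikes If `TRUE`, run the spike-clipping pre-pass.
#' @param spike_clip_sd Clipping threshold in trace standard deviations.
#' @return For a vector, a `timescale_split` list with elements `slow`,
#'   `fast`, `fs` and a filter description. For a matrix or `vm_traces`,
#'   a list with matrices `slow` and `fast`.
#' @examples
#' t <- seq(0, 10, by = 1e-3)
#' x <- sin(2 * pi * t) + 0.2 * rnorm(length(t))
#' sp <- decompose_vm(x, fs = 1000)
#' @export
decompose_vm <- function(x, fs = NULL, slow_band = c(0.2, 5), fast_cutoff = 5,
                         order = 3, clip_spikes = FALSE, spike_clip_sd = 5) {
  if (inherits(x, "vm_traces")) {
    fs <- x$fs
    x <- x$vm
  }
  if (is.null(fs)) abort("`fs` must be given for plain numeric input.")
  if (fs <= 2 * max(slow_band[2], fast_cutoff)) {
    abort(sprintf("Sampling rate %g Hz is too low for a %g Hz cutoff.", fs,
                  max(slow_band[2], fast_cutoff)))
  }
  if (is.matrix(x)) {
    slow <- apply(x, 2, decompose_one, fs = fs, slow_band = slow_band,
                  fast_cutoff = fast_cutoff, order = order,
                  clip_spikes = clip_spikes, spike_clip_sd = spike_clip_sd,
                  component = "slow")
    fast <- apply(x, 2, decompose_one, fs = fs, slow_band = slow_band,
                  fast_cutoff = fast_cutoff, order = order,
                  clip_spikes = clip_spikes, spike_clip_sd = spike_clip_sd,
                  component = "fast")
    return(list(slow = slow, fast = fast, fs = fs))
  }
  structure(
    list(slow = decompose_one(x, fs, slow_band, fast_cutoff, order,
                              clip_spikes, spike_clip_sd, "slow"),
         fast = decompose_one(x, fs, slow_band, fast_cutoff, order,
                              clip_spikes, spike_clip_sd, "fast"),
         fs = fs,
         filter = list(order = order, slow_band = slow_band,
                       fast_cutoff = fast_cutoff, bidirectional = TRUE)),
    class = "timescale_split")
}

decompose_one <- function(x, fs, slow_band, fast_cutoff, order,
                          clip_spikes, spike_clip_sd, component) {
  n <- length(x)
  min_len <- ceiling(3 * fs / (2 * pi * slow_band[1]))
  if (n < min_len) {
    abort(sprintf("Trace too short for the %g Hz slow cutoff: need >= %d samples, got %d.",
                  slow_band[1], min_len, n))
  }
  if (clip_spikes) x <- clip_action_potentials(x, spike_clip_sd)
  if (component == "slow") {
    butter_filtfilt(x, fs, slow_band, type = "pass", order = order)
  } else {
    butter_filtfilt(x, fs, fast_cutoff, type = "high", order = order)
  }
}

# Clip samples beyond mean + nsd * sd and linearly interpolate across them.
clip_action_potentials <- function(x, nsd = 5) {
  thr <- mean(x) + nsd * sd(x)
  bad <- which(x > thr)
  if (!length(bad)) return(x)
  good <- setdiff(seq_along(x), bad)
  x[bad] <- stats::approx(good, x[good], xout = bad, rule = 2)$y
  x
}

#' Pearson correlation coefficient
#'
#' Standard product-moment correlation with explicit validation: both inputs
#' must have equal length of at least two and nonzero variance.
#'
#' @param x,y Numeric vectors.
#' @return Correlation in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("`x` and `y` must have equal length.")
  if (length(x) < 2) abort("Need at least 2 observations.")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("Correlation undefined: an input has zero variance.")
  }
  cor(x, y)
}

#' Sliding-window correlation of two fast components
#'
#' Pearson correlation computed in a temporal window moving along the
#' traces, for a range of lags; the zero-lag trace is the row used to track
#' how shared synaptic input waxes and wanes through the motor rhythm.
#' Windowed moments are accumulated with cumulative sums, so cost is linear
#' per lag.
#'
#' @param x,y Numeric vectors (fast components) at rate `fs`.
#' @param fs Sampling rate, Hz.
#' @param window Window length, s.
#' @param step Window step, s.
#' @param max_lag Maximum lag magnitude, s (`y` is shifted against `x`).
#' @return A `sliding_corr` list: `time` (window centers, s), `lag` (s),
#'   `correlogram` (lag x time matrix) and `zero_lag`, a tibble with
#'   columns `time`, `r`.
#' @export
sliding_correlation <- function(x, y, fs, window = 0.4, step = 0.01,
                                max_lag = 0.1) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  w <- as.integer(round(window * fs))
  if (w < 10) abort("Window shorter than 10 samples is degenerate.")
  if (w >= n) abort("`window` must be shorter than the trace.")
  L <- as.integer(round(max_lag * fs))
  step_samp <- max(1L, as.integer(round(step * fs)))
  starts <- seq(1L + L, n - w + 1L - L, by = step_samp)
  if (!length(starts)) abort("Trace too short for this window and max_lag.")
  lags <- seq(-L, L)
  centers <- (starts - 1 + (w - 1) / 2) / fs

  sx <- cumsum(c(0, x))
  sx2 <- cumsum(c(0, x^2))
  sy <- cumsum(c(0, y))
  sy2 <- cumsum(c(0, y^2))
  Sx <- sx[starts + w] - sx[starts]
  varx <- pmax(sx2[starts + w] - sx2[starts] - Sx^2 / w, 0)

  cg <- matrix(NA_real_, nrow = length(lags), ncol = length(starts))
  for (li in seq_along(lags)) {
    l <- lags[li]
    ys <- starts + l
    Sy <- sy[ys + w] - sy[ys]
    vary <- pmax(sy2[ys + w] - sy2[ys] - Sy^2 / w, 0)
    i0 <- max(1L, 1L - l)
    i1 <- min(n, n - l)
    cz <- cumsum(c(0, x[i0:i1] * y[(i0 + l):(i1 + l)]))
    Sxy <- cz[starts + w - i0 + 1L] - cz[starts - i0 + 1L]
    num <- Sxy - Sx * Sy / w
    den <- sqrt(varx * vary)
    cg[li, ] <- ifelse(den > 0, num / den, NA_real_)
  }
  structure(
    list(time = centers, lag = lags / fs, correlogram = cg,
         zero_lag = tibble(time = centers, r = cg[L + 1L, ])),
    class = "sliding_corr")
}

#' Shuffle null for a pairwise correlation
#'
#' Builds the chance distribution of the Pearson correlation by circularly
#' shifting one trace by a random offset (uniform between `shift_range[1]`
#' and `shift_range[2]` seconds) and recomputing the coefficient; the 95%
#' confidence limits are the null mean plus/minus 1.96 standard deviations.
#' The circular shift preserves each trace's marginal distribution exactly.
#'
#' @param x,y Numeric vectors at rate `fs`.
#' @param fs Sampling rate, Hz.
#' @param n_shuffles Number of shuffles.
#' @param shift_range Random shift range, s.
#' @param seed Optional integer seed.
#' @return A list: `null_mean`, `null_sd`, `lower`, `upper`, `null_r`
#'   (the full null sample) and `observed` (the unshuffled correlation).
#' @export
shuffle_null <- function(x, y, fs, n_shuffles = 200, shift_range = c(0.5, 2),
                         seed = NULL) {
  n <- length(x)
  if (length(y) != n) abort("`x` and `y` must have equal length.")
  max_shift <- as.integer(round(shift_range[2] * fs))
  if (max_shift >= n) abort("`shift_range` exceeds the trace length.")
  set_seed_if(seed)
  shifts <- as.integer(round(runif(n_shuffles, shift_range[1] * fs, max_shift)))
  xm <- x - mean(x)
  ym <- y - mean(y)
  denom <- (n - 1) * sd(x) * sd(y)
  if (denom == 0) abort("Correlation undefined: an input has zero variance.")
  null_r <- vapply(shifts, function(s) {
    ys <- c(ym[(s + 1):n], ym[1:s])
    sum(xm * ys) / denom
  }, numeric(1))
  m <- mean(null_r)
  s <- sd(null_r)
  list(null_mean = m, null_sd = s, lower = m - 1.96 * s, upper = m + 1.96 * s,
       null_r = null_r, observed = sum(xm * ym) / denom)
}

#' Phase lag between two slow components
#'
#' The lag of the peak of the cross-correlation function of the two slow
#' (band-passed) traces, expressed in degrees of the dominant oscillation
#' period and wrapped to `[0, 360)`. Both traces must be rhythmic: the
#' dominant spectral peak must stand out from the broadband background
#' (peak power at least `rhythm_floor` times the median periodogram power).
#'
#' @param slow_x,slow_y Slow components at rate `fs`.
#' @param fs Sampling rate, Hz.
#' @param rhythm_floor Peak-to-median periodogram power ratio required to
#'   call a trace rhythmic.
#' @return A list: `phase_deg` in `[0, 360)`, `period` (s), `lag` (s).
#' @export
pair_phase <- function(slow_x, slow_y, fs, rhythm_floor = 50) {
  n <- length(slow_x)
  if (length(slow_y) != n) abort("`slow_x` and `slow_y` must have equal length.")
  dom <- function(z) {
    spec <- Mod(fft(z - mean(z))[2:floor(n / 2)])^2
    pk <- which.max(spec)
    if (spec[pk] < rhythm_floor * median(spec)) {
      abort("Phase undefined: trace is not rhythmic (no dominant spectral peak).")
    }
    pk / (n / fs) # Hz
  }
  f0 <- dom(slow_x)
  dom(slow_y)
  period <- 1 / f0
  max_lag <- min(n - 1, as.integer(round(period * fs)))
  cc <- stats::ccf(slow_x, slow_y, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)
  lag <- cc$lag[which.max(cc$acf)] / fs
  list(phase_deg = wrap_degrees(-lag / period * 360), period = period,
       lag = lag)
}

#' Quiescence mask from slow-component envelope
#'
#' Marks epochs in which the slow-component envelope power falls below a
#' fraction of the trace-wide power, so pairwise summaries can exclude
#' quiescent stretches where there is no network activity to correlate.
#' The envelope is the RMS of the slow component in non-overlapping epochs.
#'
#' @param slow Slow component vector, or a matrix (one column per cell, the
#'   mask then requires *all* cells quiescent).
#' @param fs Sampling rate, Hz.
#' @param threshold Quiescence threshold as a fraction of trace-wide RMS.
#' @param epoch Epoch length, s.
#' @return Logical vector, `TRUE` where quiescent.
#' @export
quiescence_mask <- function(slow, fs, threshold = 0.1, epoch = 1) {
  if (is.matrix(slow)) {
    masks <- apply(slow, 2, quiescence_mask, fs = fs, threshold = threshold,
                   epoch = epoch)
    return(rowSums(masks) == ncol(slow))
  }
  n <- length(slow)
  e <- max(1L, as.integer(round(epoch * fs)))
  # merge a partial trailing epoch into the last full one
  idx <- pmin(ceiling(seq_len(n) / e), max(1L, n %/% e))
  rms_all <- sqrt(mean(slow^2))
  if (rms_all == 0) {
    warn("All epochs are quiescent; no active samples remain.")
    return(rep(TRUE, n))
  }
  ep_rms <- sqrt(tapply(slow^2, idx, mean))
  mask <- (ep_rms < threshold * rms_all)[idx]
  if (all(mask)) warn("All epochs are quiescent; no active samples remain.")
  unname(mask)
}

#' Per-pair slow/fast correlation summary
#'
#' The central decoupling measurement: for every cell pair, the Pearson
#' correlation of the slow (0.2-5 Hz) components and of the fast (>5 Hz)
#' components, optionally with a circular-shift shuffle null and its 95%
#' confidence limits per pair.
#'
#' @param x A `vm_traces` object or numeric matrix (columns = cells).
#' @param fs Sampling rate (ignored for `vm_traces`).
#' @param n_shuffles Shuffles per pair for the null (0 disables).
#' @param mask_quiescence If `TRUE`, fast correlations are computed on
#'   non-quiescent samples only.
#' @param seed Optional integer seed for the shuffles.
#' @inheritParams quiescence_mask
#' @return A tibble with one row per unordered pair: `cell_x`, `cell_y`,
#'   `slow_r`, `fast_r`, and when `n_shuffles > 0` also `null_mean`,
#'   `null_sd`, `lower`, `upper`, `significant`.
#' @examples
#' top <- build_fixed_indegree(20, 4, 10, seed = 1)
#' sim <- simulate_network(top, drive_params(duration = 20), seed = 1)
#' vm_pair_correlations(sim$vm)
#' @export
vm_pair_correlations <- function(x, fs = NULL, n_shuffles = 0,
                                 mask_quiescence = FALSE, threshold = 0.1,
                                 seed = NULL) {
  if (inherits(x, "vm_traces")) {
    fs <- x$fs
    cells <- x$cells
    x <- x$vm
  } else {
    cells <- colnames(x)
    if (is.null(cells)) cells <- paste0("cell", seq_len(ncol(x)))
  }
  comp <- decompose_vm(x, fs)
  active <- if (mask_quiescence) {
    !quiescence_mask(comp$slow, fs, threshold = threshold)
  } else {
    rep(TRUE, nrow(x))
  }
  slow_m <- cor(comp$slow)
  fast_m <- cor(comp$fast[active, , drop = FALSE])
  pairs <- pair_index(ncol(x))
  out <- tibble(
    cell_x = cells[pairs[, 1]], cell_y = cells[pairs[, 2]],
    slow_r = slow_m[pairs], fast_r = fast_m[pairs])
  if (n_shuffles > 0) {
    nulls <- purrr::map2(pairs[, 1], pairs[, 2], function(i, j) {
      sn <- shuffle_null(comp$fast[active, i], comp$fast[active, j], fs,
                         n_shuffles = n_shuffles,
                         seed = if (is.null(seed)) NULL
                                else derive_seed(seed, i * 1000L + j))
      tibble(null_mean = sn$null_mean, null_sd = sn$null_sd,
             lower = sn$lower, upper = sn$upper)
    })
    out <- dplyr::bind_cols(out, dplyr::bind_rows(nulls))
    out$significant <- out$fast_r < out$lower | out$fast_r > out$upper
  }
  out
}

#' Rate dependence of the fast correlation
#'
#' Under active decorrelation the suppression of shared input tracks the
#' firing rate of the drive, so the sliding fast-correlation trace should
#' be anti-correlated with the slow (low-pass filtered) membrane potential.
#' This computes the Pearson correlation between the zero-lag sliding
#' correlation and the low-passed Vm resampled at the window centers, plus
#' a circular-shift shuffle distribution.
#'
#' @param zero_lag Tibble from [sliding_correlation()] (`time`, `r`).
#' @param lowpass_vm Low-pass filtered Vm vector sampled at `fs` (typically
#'   the mean of the pair's slow components).
#' @param fs Sampling rate of `lowpass_vm`, Hz.
#' @param n_shuffles Number of circular shifts of the zero-lag trace.
#' @param shift_range Shift range, s.
#' @param seed Optional integer seed.
#' @return A list: `r` (observed dependence), `null_r` (shuffle sample).
#' @export
fastcorr_rate_dependence <- function(zero_lag, lowpass_vm, fs,
                                     n_shuffles = 20, shift_range = c(0.5, 2),
                                     seed = NULL) {
  idx <- as.integer(round(zero_lag$time * fs)) + 1L
  if (any(idx < 1L | idx > length(lowpass_vm))) {
    abort("Zero-lag window centers fall outside the Vm trace after resampling.")
  }
  vm_w <- lowpass_vm[idx]
  rw <- zero_lag$r
  ok <- is.finite(rw)
  rw <- rw[ok]
  vm_w <- vm_w[ok]
  set_seed_if(seed)
  # shifts expressed in window steps
  dt_w <- median(diff(zero_lag$time))
  smin <- max(1L, as.integer(round(shift_range[1] / dt_w)))
  smax <- max(smin + 1L, as.integer(round(shift_range[2] / dt_w)))
  smax <- min(smax, length(rw) - 1L)
  shifts <- sample(seq(smin, smax), n_shuffles, replace = TRUE)
  null_r <- vapply(shifts, function(s) {
    cor(c(rw[(s + 1):length(rw)], rw[1:s]), vm_w)
  }, numeric(1))
  list(r = cor(rw, vm_w), null_r = null_r)
}
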