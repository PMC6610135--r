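# Ground-truth-labelled generators that emulate the statistical structure
# each analysis stage assumes, so the pipeline is testable without recorded
# data and independently of the network simulator.

band_noise <- function(n, fs, band = c(5, 100), sd_target = 1) {
  x <- rnorm(n)
  hi <- min(band[2], fs / 2 * 0.95)
  y <- butter_filtfilt(x, fs, c(band[1], hi), type = "pass")
  y / sd(y) * sd_target
}

#' Synthetic membrane-potential pair with controlled shared input
#'
#' Two traces built as a slow sinusoidal envelope (with per-cell phase
#' offsets) plus band-limited Gaussian fast noise mixed from a common and
#' an independent source with weights `sqrt(c)` and `sqrt(1 - c)`, so the
#' expected fast-component correlation equals the shared fraction `c` by
#' construction, while the expected slow correlation is
#' `cos(phase_offset[2] - phase_offset[1])`.
#'
#' @param shared_fraction Shared-input fraction `c` in `[0, 1]`.
#' @param duration Trace length, s.
#' @param fs Sampling rate, Hz.
#' @param slow_freq Envelope frequency, Hz.
#' @param slow_amp Envelope amplitude, mV.
#' @param phase_offset Envelope phase per cell, radians (length 2).
#' @param fast_sd Fast-noise standard deviation, mV.
#' @param fast_band Fast-noise band, Hz.
#' @param mean_vm Resting offset, mV.
#' @param seed Optional integer seed.
#' @return A list: `vm` (a `vm_traces` with 2 cells) and `truth`
#'   (`fast_r`, `slow_r` targets and the generating parameters).
#' @examples
#' pair <- make_shared_input_pair(0.36, duration = 10, seed = 1)
#' pair$truth$fast_r
#' @export
make_shared_input_pair <- function(shared_fraction, duration = 20, fs = 1000,
                                   slow_freq = 1, slow_amp = 5,
                                   phase_offset = c(0, 0), fast_sd = 1,
                                   fast_band = c(5, 100), mean_vm = -60,
                                   seed = NULL) {
  check_scalar_number(shared_fraction, "shared_fraction", min = 0, max = 1)
  set_seed_if(seed)
  n <- as.integer(round(duration * fs))
  t <- (seq_len(n) - 1) / fs
  common <- band_noise(n, fs, fast_band, fast_sd)
  vm <- vapply(1:2, function(i) {
    indep <- band_noise(n, fs, fast_band, fast_sd)
    mean_vm + slow_amp * sin(2 * pi * slow_freq * t + phase_offset[i]) +
      sqrt(shared_fraction) * common + sqrt(1 - shared_fraction) * indep
  }, numeric(n))
  list(vm = new_vm_traces(vm, fs, cells = c("cell1", "cell2")),
       truth = list(fast_r = shared_fraction,
                    slow_r = cos(phase_offset[2] - phase_offset[1]),
                    slow_freq = slow_freq, slow_amp = slow_amp,
                    fast_sd = fast_sd, fast_band = fast_band))
}

#' Synthetic phase-tuned spiking population
#'
#' Independent inhomogeneous Poisson units whose rates are von Mises tuned
#' to a common rhythm: unit `i` fires at
#' `lambda_i(t) = base_rate * exp(kappa_i (cos(theta(t) - mu_i) - 1))`
#' with `theta(t) = 2 pi f t`. `kappa = 0` gives phase-uniform units. A
#' sinusoidal reference trace at the rhythm frequency is emitted for
#' Hilbert-phase analysis.
#'
#' @param n_units Number of units.
#' @param preferred_phase Per-unit preferred phase, radians (recycled).
#' @param kappa Per-unit concentration (recycled; 0 = untuned).
#' @param base_rate Peak firing rate at the preferred phase, spikes/s.
#' @param frequency Rhythm frequency, Hz.
#' @param duration Recording length, s.
#' @param fs Reference-trace sampling rate, Hz.
#' @param seed Optional integer seed.
#' @return A list: `spikes` (`spike_trains`), `reference` (tibble `time`,
#'   `signal`), `fs`, `truth` (per-unit tibble of `mu`, `kappa`).
#' @export
make_tuned_population <- function(n_units = 20,
                                  preferred_phase = seq(0, 2 * pi,
                                                        length.out = n_units + 1)[-1],
                                  kappa = 2, base_rate = 20, frequency = 1,
                                  duration = 20, fs = 1000, seed = NULL) {
  if (base_rate < 0) abort("`base_rate` must be nonnegative.")
  set_seed_if(seed)
  mu <- rep_len(preferred_phase, n_units)
  kap <- rep_len(kappa, n_units)
  lam_fun <- function(t, i) {
    base_rate * exp(kap[i] * (cos(2 * pi * frequency * t - mu[i]) - 1))
  }
  unit <- integer(0)
  time <- numeric(0)
  for (i in seq_len(n_units)) {
    n_cand <- rpois(1, base_rate * duration)
    tc <- runif(n_cand, 0, duration)
    keep <- runif(n_cand) < lam_fun(tc, i) / base_rate
    time <- c(time, tc[keep])
    unit <- c(unit, rep(i, sum(keep)))
  }
  tgrid <- seq(0, duration, by = 1 / fs)
  list(spikes = new_spike_trains(unit, time, interval = c(0, duration),
                                 units = seq_len(n_units)),
       reference = tibble(time = tgrid,
                          signal = cos(2 * pi * frequency * tgrid)),
       fs = fs,
       truth = tibble(unit = seq_len(n_units), mu = mu, kappa = kap))
}

#' Synthetic intracellular trace with a planted synaptic connection
#'
#' Membrane potential built as an Ornstein-Uhlenbeck background (standard
#' deviation `noise_sd`, correlation time `noise_tau_ms`) plus one
#' exponentially decaying postsynaptic potential of known amplitude and
#' decay constant after every presynaptic spike (homogeneous Poisson at
#' `rate`). Negative amplitudes plant an IPSP, positive an EPSP, zero an
#' unconnected control.
#'
#' @param rate Presynaptic firing rate, spikes/s.
#' @param psp_amplitude PSP peak amplitude, mV (signed).
#' @param tau_ms PSP decay constant, ms.
#' @param n_spikes Target number of presynaptic spikes (sets the duration).
#' @param fs Sampling rate, Hz.
#' @param noise_sd Background fluctuation SD, mV. The default of 0.5 mV
#'   matches quiescent-state intracellular noise in sharp-electrode
#'   recordings; raise it to emulate fluctuations during network activity.
#' @param noise_tau_ms Background correlation time, ms.
#' @param mean_vm Resting potential, mV.
#' @param delay_ms Synaptic latency from spike to PSP onset, ms.
#' @param seed Optional integer seed.
#' @return A list: `vm` (numeric trace), `fs`, `spike_times`, `truth`
#'   (amplitude, tau_ms, delay_ms).
#' @examples
#' cp <- make_connected_pair(psp_amplitude = -0.5, n_spikes = 200, seed = 1)
#' @export
make_connected_pair <- function(rate = 10, psp_amplitude = -0.5, tau_ms = 5,
                                n_spikes = 2000, fs = 2000, noise_sd = 0.5,
                                noise_tau_ms = 5, mean_vm = -60,
                                delay_ms = 2, seed = NULL) {
  if (tau_ms <= 0) abort("`tau_ms` must be positive.")
  set_seed_if(seed)
  duration <- n_spikes / rate + 2
  n <- as.integer(round(duration * fs))
  dt_ms <- 1000 / fs
  # OU background: AR(1) with the matching stationary variance
  a <- exp(-dt_ms / noise_tau_ms)
  bg <- stats::filter(rnorm(n, sd = noise_sd * sqrt(1 - a^2)), a,
                      method = "recursive")
  bg <- as.numeric(bg)
  # presynaptic Poisson train
  spike_times <- sort(runif(rpois(1, rate * duration), 0, duration))
  # PSP kernel applied by AR(1) recursion on the spike impulse train
  onset <- spike_times + delay_ms / 1000
  idx <- as.integer(round(onset * fs)) + 1L
  idx <- idx[idx >= 1L & idx <= n]
  tab <- tabulate(idx, nbins = n)
  psp <- as.numeric(stats::filter(psp_amplitude * tab,
                                  exp(-dt_ms / tau_ms),
                                  method = "recursive"))
  list(vm = mean_vm + bg + psp, fs = fs, spike_times = spike_times,
       truth = list(amplitude = psp_amplitude, tau_ms = tau_ms,
                    delay_ms = delay_ms, noise_sd = noise_sd))
}
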