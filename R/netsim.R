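#' Parameter constructors for the network model
#'
#' Defaults follow the common-drive model: leaky integrate-and-fire cells
#' with membrane capacitance 250 pF, leak conductance 16.67 nS and resting
#' potential -60 mV. Receivers have spiking disabled; inhibitory
#' interneurons spike at -50 mV, reset to -60 mV and are refractory for
#' 2 ms. Synapses are exponentially decaying conductances (tau = 1 ms) with
#' reversal potentials 0 mV (excitatory) and -80 mV (inhibitory), and a
#' 1 ms transmission delay.
#'
#' @param capacitance Membrane capacitance, pF.
#' @param leak_conductance Leak conductance, nS.
#' @param resting_potential Resting (leak reversal) potential, mV.
#' @param spike_threshold Interneuron spike threshold, mV.
#' @param reset_potential Post-spike reset potential, mV.
#' @param refractory Absolute refractory period, ms.
#' @return A parameter list.
#' @export
cell_params <- function(capacitance = 250, leak_conductance = 16.67,
                        resting_potential = -60, spike_threshold = -50,
                        reset_potential = -60, refractory = 2) {
  check_scalar_number(capacitance, "capacitance", min = 1e-9)
  check_scalar_number(leak_conductance, "leak_conductance", min = 1e-9)
  if (spike_threshold <= reset_potential) {
    abort("`spike_threshold` must exceed `reset_potential`.")
  }
  structure(list(capacitance = capacitance, leak_conductance = leak_conductance,
                 resting_potential = resting_potential,
                 spike_threshold = spike_threshold,
                 reset_potential = reset_potential, refractory = refractory),
            class = "cell_params")
}

#' @rdname cell_params
#' @param tau Synaptic conductance decay time constant, ms.
#' @param e_exc,e_inh Excitatory / inhibitory reversal potentials, mV.
#' @param g_exc,g_inh Peak synaptic conductances, nS. The dense-vs-sparse
#'   size sweep uses 10 nS excitation; the motif studies use 5 nS excitation
#'   and 15 nS inhibition (approximate E/I current balance at rest).
#' @param delay Spike transmission delay, ms.
#' @export
synapse_params <- function(tau = 1, e_exc = 0, e_inh = -80,
                           g_exc = 10, g_inh = 15, delay = 1) {
  check_scalar_number(tau, "tau", min = 1e-9)
  if (!(e_inh < e_exc)) abort("`e_inh` must be below `e_exc`.")
  structure(list(tau = tau, e_exc = e_exc, e_inh = e_inh,
                 g_exc = g_exc, g_inh = g_inh, delay = delay),
            class = "synapse_params")
}

#' @rdname cell_params
#' @param rate_mean Mean drive rate r0, spikes/s.
#' @param rate_amplitude Sinusoidal modulation amplitude r1, spikes/s. The
#'   instantaneous rate `r0 + r1 sin(2 pi f t)` is clipped at zero.
#' @param frequency Modulation frequency, Hz.
#' @param duration Drive duration, s.
#' @export
drive_params <- function(rate_mean = 12, rate_amplitude = 10, frequency = 1,
                         duration = 60) {
  check_scalar_number(rate_mean, "rate_mean", min = 0)
  check_scalar_number(rate_amplitude, "rate_amplitude", min = 0)
  check_scalar_number(frequency, "frequency", min = 0)
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0) {
    abort("`duration` must be a positive number of seconds.")
  }
  structure(list(rate_mean = rate_mean, rate_amplitude = rate_amplitude,
                 frequency = frequency, duration = duration),
            class = "drive_params")
}

#' Sample rhythmically modulated Poisson spike trains
#'
#' Each unit is an independent realization of an inhomogeneous Poisson
#' process with rate `lambda(t) = max(0, r0 + r1 sin(2 pi f t))`, sampled
#' exactly by thinning against `lambda_max = r0 + r1`.
#'
#' @param drive A [drive_params()].
#' @param n_units Number of independent units.
#' @param seed Optional integer seed.
#' @return A `spike_trains` tibble with columns `unit`, `time` (seconds),
#'   carrying the recording interval and unit ids as attributes.
#' @examples
#' st <- sample_inhomogeneous_poisson(drive_params(duration = 2), 5, seed = 1)
#' @export
sample_inhomogeneous_poisson <- function(drive, n_units, seed = NULL) {
  stopifnot(inherits(drive, "drive_params"))
  n_units <- check_count(n_units, "n_units")
  set_seed_if(seed)
  lambda_max <- drive$rate_mean + drive$rate_amplitude
  counts <- rpois(n_units, lambda_max * drive$duration)
  unit <- rep(seq_len(n_units), counts)
  t_cand <- runif(sum(counts), 0, drive$duration)
  lam <- pmax(0, drive$rate_mean +
                drive$rate_amplitude * sin(2 * pi * drive$frequency * t_cand))
  keep <- runif(length(t_cand)) < lam / lambda_max
  new_spike_trains(unit[keep], t_cand[keep], interval = c(0, drive$duration),
                   units = seq_len(n_units))
}

new_spike_trains <- function(unit, time, interval, units = NULL) {
  ord <- order(unit, time)
  out <- tibble(unit = as.integer(unit[ord]), time = as.numeric(time[ord]))
  structure(out, interval = interval,
            units = if (is.null(units)) sort(unique(out$unit)) else units,
            class = c("spike_trains", class(tibble())))
}

#' @export
print.spike_trains <- function(x, ...) {
  iv <- attr(x, "interval")
  cat(sprintf("<spike_trains> %d units, %d spikes on [%g, %g] s\n",
              length(attr(x, "units")), nrow(x), iv[1], iv[2]))
  NextMethod()
}

new_vm_traces <- function(vm, fs, t0 = 0, cells = NULL) {
  if (is.null(cells)) cells <- paste0("cell", seq_len(ncol(vm)))
  colnames(vm) <- cells
  structure(list(vm = vm, fs = fs, t0 = t0, cells = cells),
            class = "vm_traces")
}

#' @export
print.vm_traces <- function(x, ...) {
  cat(sprintf("<vm_traces> %d cells x %d samples at %g Hz (%.1f s)\n",
              ncol(x$vm), nrow(x$vm), x$fs, nrow(x$vm) / x$fs))
  invisible(x)
}

#' @rdname simulate_network
#' @param x A `vm_traces` object.
#' @param ... Unused.
#' @export
tidy.vm_traces <- function(x, ...) {
  tibble(
    time = rep(x$t0 + (seq_len(nrow(x$vm)) - 1) / x$fs, times = ncol(x$vm)),
    cell = rep(x$cells, each = nrow(x$vm)),
    vm = as.vector(x$vm))
}

#' @export
as_tibble.vm_traces <- function(x, ...) tidy.vm_traces(x)

topology_to_csr <- function(top, n_pre) {
  if (is.null(top)) {
    return(list(ptr = integer(n_pre + 1L), idx = integer(0)))
  }
  ord <- order(top$source, top$target)
  src <- top$source[ord]
  tgt <- top$target[ord]
  counts <- tabulate(src, nbins = n_pre)
  list(ptr = as.integer(c(0L, cumsum(counts))), idx = as.integer(tgt - 1L))
}

#' Simulate the rhythmically driven network
#'
#' Integrates the conductance-based leaky integrate-and-fire model:
#' `C dV/dt = -gL (V - EL) - gE(t) (V - E_exc) - gI(t) (V - E_inh)`, where
#' each presynaptic spike increments its synapse conductance by the peak
#' value and conductances decay exponentially. Receivers never spike;
#' inhibitory interneurons (if the motif has them) spike at threshold and
#' reset. Both conductance decay and the voltage relaxation use
#' exponential-Euler updates at step `dt` (exact for conductances held
#' constant over one step).
#'
#' @param topology A `cpg_topology` (treated as excitatory drive ->
#'   receiver) or a `cpg_motif` from [build_motif()].
#' @param drive A [drive_params()].
#' @param cells A [cell_params()].
#' @param synapses A [synapse_params()].
#' @param dt Integration step, ms. Must satisfy `dt <= tau_syn / 10`.
#' @param record_fs Sampling rate of the recorded membrane potentials, Hz.
#' @param seed Integer seed; drive sampling uses a derived sub-seed so the
#'   same seed and configuration reproduce the run exactly.
#' @return A `cpg_sim` list: `vm` (receiver `vm_traces`), `source_spikes`,
#'   `inh_spikes` (or `NULL`), and the full `config`.
#' @examples
#' top <- build_fixed_indegree(20, 5, 10, seed = 1)
#' sim <- simulate_network(top, drive_params(duration = 2), seed = 1)
#' @export
simulate_network <- function(topology, drive,
                             cells = cell_params(),
                             synapses = synapse_params(),
                             dt = 0.1, record_fs = 1000, seed = NULL) {
  stopifnot(inherits(drive, "drive_params"), inherits(cells, "cell_params"),
            inherits(synapses, "synapse_params"))
  if (dt > synapses$tau / 10 + 1e-12) {
    abort(sprintf("dt = %g ms is too coarse: must be <= tau_syn / 10 = %g ms.",
                  dt, synapses$tau / 10))
  }
  if (inherits(topology, "cpg_topology")) {
    graphs <- list(drive_receiver = topology)
  } else if (inherits(topology, "cpg_motif")) {
    graphs <- topology
  } else {
    abort("`topology` must be a cpg_topology or cpg_motif.")
  }
  dr <- graphs$drive_receiver
  n_source <- attr(dr, "n_source")
  n_rec <- attr(dr, "n_receiver")
  n_inh <- if (!is.null(graphs$drive_inh)) attr(graphs$drive_inh, "n_receiver") else 0L
  if (!is.null(graphs$drive_inh) && attr(graphs$drive_inh, "n_source") != n_source) {
    abort("drive_inh and drive_receiver disagree on the drive population size.")
  }
  if (!is.null(graphs$inh_receiver) &&
      (attr(graphs$inh_receiver, "n_source") != n_inh ||
       attr(graphs$inh_receiver, "n_receiver") != n_rec)) {
    abort("inh_receiver population sizes are inconsistent with the motif.")
  }

  src_spikes <- sample_inhomogeneous_poisson(
    drive, n_source, seed = if (is.null(seed)) NULL else derive_seed(seed, 101L))

  n_steps <- as.integer(round(drive$duration * 1000 / dt))
  record_every <- as.integer(round(1000 / (record_fs * dt)))
  if (record_every < 1L) abort("`record_fs` exceeds the integration rate.")
  delay_steps <- max(1L, as.integer(round(synapses$delay / dt)))

  # off-grid drive spikes land on the next grid point with their conductance
  # increment pre-decayed by the sub-step offset (exact placement), then are
  # shifted by the transmission delay
  step_exact <- src_spikes$time * 1000 / dt
  step <- as.integer(ceiling(step_exact)) + delay_steps
  weight <- exp(-(ceiling(step_exact) - step_exact) * dt / synapses$tau)
  keep <- step < n_steps
  ord <- order(step[keep])
  ev_step <- step[keep][ord]
  ev_unit <- as.integer(src_spikes$unit[keep][ord] - 1L)
  ev_weight <- weight[keep][ord]

  dr_csr <- topology_to_csr(graphs$drive_receiver, n_source)
  di_csr <- topology_to_csr(graphs$drive_inh, n_source)
  ir_csr <- topology_to_csr(graphs$inh_receiver, max(n_inh, 1L))
  ii_csr <- topology_to_csr(graphs$inh_inh, max(n_inh, 1L))

  res <- lif_network_cpp(
    dt, n_steps, record_every, n_rec, n_inh,
    cells$capacitance, cells$leak_conductance, cells$resting_potential,
    cells$spike_threshold, cells$reset_potential, cells$refractory,
    synapses$tau, synapses$e_exc, synapses$e_inh, delay_steps,
    synapses$g_exc, synapses$g_exc, synapses$g_inh, synapses$g_inh,
    ev_step, ev_unit, ev_weight,
    dr_csr$ptr, dr_csr$idx, di_csr$ptr, di_csr$idx,
    ir_csr$ptr, ir_csr$idx, ii_csr$ptr, ii_csr$idx)

  vm <- new_vm_traces(res$vm, fs = 1000 / (record_every * dt),
                      cells = paste0("rec", seq_len(n_rec)))
  inh_spikes <- if (n_inh > 0) {
    new_spike_trains(res$inh_spike_unit, res$inh_spike_time,
                     interval = c(0, drive$duration), units = seq_len(n_inh))
  }
  structure(
    list(vm = vm, source_spikes = src_spikes, inh_spikes = inh_spikes,
         config = list(drive = unclass(drive), cells = unclass(cells),
                       synapses = unclass(synapses), dt = dt,
                       record_fs = record_fs, seed = seed,
                       n_source = n_source, n_receiver = n_rec, n_inh = n_inh,
                       motif = if (inherits(topology, "cpg_motif"))
                         attr(topology, "spec")$motif else "ff_exc")),
    class = "cpg_sim")
}

#' @export
print.cpg_sim <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<cpg_sim> motif %s: %d sources -> %d receivers%s, %.1f s at %g Hz\n",
              cfg$motif, cfg$n_source, cfg$n_receiver,
              if (cfg$n_inh > 0) sprintf(" (+%d interneurons)", cfg$n_inh) else "",
              cfg$drive$duration, cfg$record_fs))
  invisible(x)
}
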