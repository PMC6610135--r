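---
title: "Inferring common-drive network architecture from two-timescale correlations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring common-drive network architecture from two-timescale correlations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(cpgnet)
```

## The inference problem

During rhythmic motor behaviour, most spinal neurons receive an oscillatory
synaptic drive whose anatomical source — a central pattern generator (CPG)
network — cannot be observed directly. `cpgnet` implements the dynamical
route to that anatomy: if a *small* drive population projects *densely and
divergently* onto the receiving motoneurons and premotor interneurons, any
two receivers share most of their synaptic input and their membrane
potentials must be correlated at the millisecond (synaptic) timescale. If
instead the drive population is *large* with *sparse convergent* wiring,
two receivers share almost nothing even though both follow the same slow
rhythm. Pairwise recordings therefore separate the two architectures by
comparing correlations on two timescales:

* the **slow** band (0.2–5 Hz): rate modulation, i.e. functional
  relatedness to the motor rhythm;
* the **fast** band (> 5 Hz): shared synaptic fluctuations, i.e. direct
  evidence of common connections.

For a bipartite projection with constant in-degree $k$ from $n_1$ sources,
density is $\xi = k/n_1$, sparseness is $\rho = 1-\xi$, the expected number
of sources shared by two receivers is hypergeometric with mean $k^2/n_1$,
and the expected fast-timescale correlation is the shared-input fraction

$$\mathbb{E}[R_\text{fast}] \approx \frac{k}{n_1}.$$

A strong slow correlation with a weak fast correlation ("decoupling of
timescales") therefore implies either a sparse convergent drive or an
active mechanism cancelling the shared input.

## The network model

`simulate_network()` integrates non-spiking conductance-based leaky
integrate-and-fire receivers (and, for the inhibition motifs, spiking
interneurons):

$$C\frac{dV}{dt} = -g_L(V - E_L) - g_E(t)(V - E_\text{exc}) - g_I(t)(V - E_\text{inh})$$

with $C = 250$ pF, $g_L = 16.67$ nS, $E_L = -60$ mV, synaptic conductances
that jump by a fixed peak value at each presynaptic spike and decay
exponentially with $\tau = 1$ ms, and reversal potentials 0 mV
(excitatory) and $-80$ mV (inhibitory). Interneurons spike at $-50$ mV,
reset to $-60$ mV and are refractory for 2 ms. The drive is an
inhomogeneous Poisson population with rate
$\lambda(t) = \max\{0,\, r_0 + r_1 \sin(2\pi f t)\}$, sampled exactly by
thinning. Two parameter sets matter:

| quantity | size sweep | motif studies |
|---|---|---|
| drive $r_0 \pm r_1$ | 12 ± 10 spikes/s | 80 ± 70 spikes/s |
| excitatory peak | 10 nS | 5 nS |
| inhibitory peak | — | 15 nS |
| receivers | 30 | 100 (+100 interneurons) |

The 5/15 nS pairing balances the per-spike currents at rest
($5\,\text{nS}\times60\,\text{mV} = 15\,\text{nS}\times20\,\text{mV} =
300$ pA). The drive population size for the motif studies is a
configuration value (`motif_spec(n_source = )`, default 100, matching the
receiver and interneuron populations); only its sparseness (0.5) is fixed
by the study design.

### Numerical scheme

Conductances decay by the exact factor $e^{-\Delta t/\tau}$; the voltage
relaxes exponentially toward its instantaneous equilibrium
$(g_L E_L + g_E E_\text{exc} + g_I E_\text{inh})/g_\text{tot}$, which is
exact while conductances are constant within a step. Off-grid drive spikes
are placed on the next grid point with their conductance increment
pre-decayed by the sub-step offset, so spike timing is not quantized to
the grid. At the default $\Delta t = 0.1$ ms, halving the step changes
receiver trajectories by ~0.05 mV RMS. Spike transmission is delayed by
1 ms (configurable); a strictly positive delay keeps recurrent inhibition
well-posed. All randomness flows from a single integer seed through
deterministic sub-seeds, and identical seed + configuration reproduces
runs bit for bit.

```{r quick-sim}
top <- build_fixed_indegree(20, 30, k = 10, seed = 1)
glance(top)
sim <- simulate_network(top, drive_params(12, 10, 1, duration = 20),
                        synapses = synapse_params(g_exc = 10), seed = 1)
pc <- vm_pair_correlations(sim$vm)
c(fast = mean(pc$fast_r), slow = mean(pc$slow_r))
```

## The analysis pipeline

`decompose_vm()` splits each trace with zero-phase (forward–backward)
3-pole Butterworth filters: slow = 0.2–5 Hz band-pass, fast = 5 Hz
high-pass. The band-pass is implemented as a cascade of the order-3
high-pass and low-pass sections: a directly designed band-pass with a
0.2 Hz corner at 1 kHz sampling has poles so close to the unit circle that
the recursion loses several decimal digits, while the cascade is well
conditioned and has the same passband. Edges are padded with an odd
reflection about three filter time constants long; an optional pre-pass
clips residual action potentials (beyond mean + 5 SD) and interpolates.

On top of the decomposition sit:

* `pearson()` and `vm_pair_correlations()` — per-pair slow/fast Pearson
  coefficients, optionally restricted to non-quiescent epochs
  (`quiescence_mask()`: slow-envelope RMS below 10% of the trace-wide RMS
  in 1 s epochs; the threshold is our operational definition, the source
  studies leave "quiescence" informal);
* `sliding_correlation()` — windowed correlation (400 ms window, 10 ms
  step, ±100 ms lags) tracking how shared input waxes and wanes;
* `shuffle_null()` — the chance distribution from circular shifts of one
  trace (uniform 0.5–2 s), with 95% limits at mean ± 1.96σ; circular
  shifting preserves the marginal distribution exactly;
* `pair_phase()` — the cross-correlation peak lag of the slow components
  in degrees of the dominant period, defined only when a trace has a
  dominant spectral peak (≥ 50× the median periodogram power — white
  noise reaches ~12× by chance, so the floor must sit well above that);
* `fastcorr_rate_dependence()` — correlation between the sliding
  fast-correlation trace and the low-pass filtered membrane potential,
  against circularly shifted surrogates.

For population spiking, `kernel_rate()` convolves spike trains with
unit-area Gaussian kernels (σ = 5 ms fast / 150 ms slow, truncated at
±5σ), `rate_correlation_matrices()` high-passes the two rate traces at
10 Hz and 0.3 Hz and assembles symmetric correlation matrices, and
`screen_rhythmic_units()` excludes units that fail the Rayleigh test
($z = NR^2$, $p = \exp[\sqrt{1+4N+4(N^2-R_N^2)}-(1+2N)]$, α = 5% per
unit; a Bonferroni flag exists but is off by default to match the
per-unit convention). Reference-rhythm phase comes from the analytic
signal (FFT Hilbert transform) of the 0.1 Hz high-passed, 150 ms
Gaussian-smoothed nerve trace; phase is reported only during ongoing
activity (the mask is the caller's, since "ongoing" depends on the
recording).

## The connectivity probe

`assess_connection()` tests whether one extracellularly recorded unit
inhibits (or excites) an intracellularly recorded cell. The estimator is
the spike-triggered **median** of the membrane potential (robust to the
skew that undetected action potentials add), z-scored by the whole-trace
mean and SD. Significance comes from interval-jitter surrogates: spike
times are redrawn uniformly within fixed 100 ms bins (preserving per-bin
counts, destroying fine timing), the surrogate median traces give a
pointwise mean and SD, and the observed extremum over the causal window
(0.5–30 ms) is compared with the distribution of the surrogates' own
extremal deviations at the ±2 SD level. Applying ±2σ to the *extremum*
distribution, rather than pointwise, keeps the false-positive rate near
its nominal level despite the search over lags.

For significant negative peaks, `fit_ipsp_decay()` fits
$z(t) = A e^{-t/\tau} + b$ from the trough over 25 ms, with $b$ anchored
to the pre-spike mean: a free baseline over so short a span is
ill-conditioned and, in testing, biased $\tau$ several-fold. A $\tau$
near 5 ms indicates glycinergic inhibition; GABAergic decay is
several-fold slower.

## Synthetic ground truth

Because the analyses must be validated without recorded data,
`make_shared_input_pair()`, `make_tuned_population()` and
`make_connected_pair()` generate traces whose target statistics are known
by construction: a Vm pair mixes common and independent band-limited
(5–100 Hz) Gaussian noise with weights $\sqrt{c}$ and $\sqrt{1-c}$ so the
fast correlation *is* the shared fraction $c$; spiking units are von
Mises-tuned inhomogeneous Poisson processes around a common rhythm; a
connected pair superposes exponential PSPs of known amplitude and decay
on an Ornstein–Uhlenbeck background (0.5 mV RMS, 5 ms correlation time —
quiescent-state intracellular noise; at markedly higher noise the stated
±20% decay-constant recovery at 2000 spikes is not attainable from a
spike-triggered median, by a Cramér–Rao argument). These generators
emulate the statistical structure the analyses assume — stationary
envelopes, Gaussian backgrounds, Poisson spiking. They do not emulate
real recordings' nonstationarity, electrode artefacts or spike-sorting
errors, so green tests certify the pipeline, not the biology.

## Reproduction workflows and problem sizes

`reproduce()` wraps the three headline computations; the sizes are chosen
so each runs in minutes on a laptop while keeping Monte-Carlo error well
inside the decision margins:

* `"size_sweep"` — sources $n \in \{10, 20, 50, 100, 200, 500\}$ at
  $k = 10$, 30 receivers, 60 s, 3 seeds. Mean fast correlation follows
  $k/n$ (log–log slope ≈ −0.9) while the slow correlation stays high.
* `"motif_comparison"` — feedforward excitation, feedforward inhibition,
  recurrent inhibition at $\rho_\text{drive} = 0.5$,
  $\rho_\text{inh} = \rho_\text{rec} = 0.9$; 30 s, 5 seeds.
* `"rate_dependence"` — the recurrent motif, 55 receiver pairs, sliding
  fast correlation against low-pass Vm with shuffled alignments and a
  two-sample Kolmogorov–Smirnov test.

## What this implementation reproduces, and what it does not

The dense/sparse dichotomy is fully reproduced: mean fast correlation
0.51 at $\rho = 0.5$, 0.02 at $\rho = 0.98$, $1/n$ decay, slow
correlations near 0.9 in both topologies. Three findings from the
published motif account differ in this reimplementation, and we report
them as genuine model-behaviour differences rather than adjusting the
model toward the expected answer:

1. **Slow correlations plateau near 0.9, not 1.** The 0.2–5 Hz band
   contains Poisson shot noise as well as the 1 Hz rhythm; at a total
   input rate of 120 spikes/s the in-band noise bounds the slow
   correlation near 0.9. The value rises toward 1 only at much higher
   input rates (the motif-study drive gives 0.98).
2. **Feedforward inhibition decorrelates here.** Interneurons sharing
   half their drive fire time-locked to common input fluctuations and
   deliver an anti-correlated copy to the receivers about 2 ms later,
   cancelling shared input below ~50 Hz (band-resolved correlations show
   reduced variance, i.e. cancellation rather than dilution). The
   published account reports no decorrelation without recurrence; which
   regime a simulation lands in depends on interneuron dynamics
   (synchrony, saturation) that the stated parameters under-determine.
   Recurrent inhibition does suppress correlations further, consistently
   across seeds, and dense inhibitory wiring enhances them — both as
   described.
3. **The rate dependence of decorrelation has the opposite sign.** Here
   the suppression is strongest in the drive troughs, so the sliding fast
   correlation correlates *positively* with the slow membrane potential;
   the published model reports anti-phase. Same root cause as (2).

The acceptance suite asserts the published values as stated, so the three
corresponding expectations fail deliberately; everything else passes.

## Known limitations

Receivers are point neurons (the source studies address electrotonic
filtering experimentally, with dual same-cell recordings, not in the
model); spike sorting is out of scope (sorted event lists are inputs);
the interneuron reset, refractory period and transmission delay are
assumptions where the model description is silent; and all statistical
calibration claims are at the stated problem sizes — much longer
recordings would expose slow drifts these tests do not probe.
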