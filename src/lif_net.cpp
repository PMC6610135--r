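#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Conductance-based LIF network integrator.
//
// Populations: an external drive population (spike times supplied), an
// optional spiking inhibitory population, and a non-spiking receiver
// population. Synapses are exponentially decaying conductances
// (exponential-Euler decay, exact); the voltage uses exponential Euler
// too (exact relaxation toward the instantaneous equilibrium, treating
// conductances as constant over one step).
// Spiking interneurons: threshold / reset / absolute refractory period.
// All spike transmission is delayed by `delay_steps` integration steps.
//
// Units: ms, mV, nS, pF (so dV = dt * I[pA] / C[pF] is in mV).
//
// Projections are passed in CSR form indexed by presynaptic unit
// (ptr has length n_pre + 1, idx holds 0-based postsynaptic targets).

// [[Rcpp::export]]
List lif_network_cpp(double dt, int n_steps, int record_every,
                     int n_rec, int n_inh,
                     double C, double gL, double EL,
                     double V_th, double V_reset, double t_ref,
                     double tau_syn, double E_exc, double E_inh,
                     int delay_steps,
                     double g_drive_rec, double g_drive_inh,
                     double g_inh_rec, double g_inh_inh,
                     IntegerVector ev_step, IntegerVector ev_unit,
                     NumericVector ev_weight,
                     IntegerVector dr_ptr, IntegerVector dr_idx,
                     IntegerVector di_ptr, IntegerVector di_idx,
                     IntegerVector ir_ptr, IntegerVector ir_idx,
                     IntegerVector ii_ptr, IntegerVector ii_idx) {
  if (delay_steps < 1) stop("delay must be at least one integration step");
  const double decay = std::exp(-dt / tau_syn);
  const int ref_steps = (int)std::round(t_ref / dt);

  std::vector<double> V_rec(n_rec, EL), gE_rec(n_rec, 0.0), gI_rec(n_rec, 0.0);
  std::vector<double> V_inh(n_inh, EL), gE_inh(n_inh, 0.0), gI_inh(n_inh, 0.0);
  std::vector<int> refr(n_inh, 0);

  // ring buffer of inhibitory spikes awaiting delivery
  std::vector< std::vector<int> > ring(delay_steps);

  const int n_samp = (n_steps + record_every - 1) / record_every;
  NumericMatrix vm(n_samp, n_rec);
  std::vector<int> inh_spike_unit;
  std::vector<double> inh_spike_time;

  const int n_ev = ev_step.size();
  int ev = 0;
  int samp = 0;

  for (int t = 0; t < n_steps; ++t) {
    // record before the update so sample times are t * dt
    if (t % record_every == 0) {
      for (int i = 0; i < n_rec; ++i) vm(samp, i) = V_rec[i];
      ++samp;
    }

    // deliver drive spikes scheduled for this step (steps pre-shifted by delay)
    while (ev < n_ev && ev_step[ev] == t) {
      int u = ev_unit[ev];
      double w = ev_weight[ev];
      for (int e = dr_ptr[u]; e < dr_ptr[u + 1]; ++e) gE_rec[dr_idx[e]] += g_drive_rec * w;
      if (n_inh > 0)
        for (int e = di_ptr[u]; e < di_ptr[u + 1]; ++e) gE_inh[di_idx[e]] += g_drive_inh * w;
      ++ev;
    }

    // deliver delayed inhibitory spikes
    if (n_inh > 0) {
      std::vector<int> &slot = ring[t % delay_steps];
      for (size_t s = 0; s < slot.size(); ++s) {
        int u = slot[s];
        for (int e = ir_ptr[u]; e < ir_ptr[u + 1]; ++e) gI_rec[ir_idx[e]] += g_inh_rec;
        for (int e = ii_ptr[u]; e < ii_ptr[u + 1]; ++e) gI_inh[ii_idx[e]] += g_inh_inh;
      }
      slot.clear();
    }

    // integrate receivers (never spike)
    for (int i = 0; i < n_rec; ++i) {
      double gtot = gL + gE_rec[i] + gI_rec[i];
      double veq = (gL * EL + gE_rec[i] * E_exc + gI_rec[i] * E_inh) / gtot;
      V_rec[i] = veq + (V_rec[i] - veq) * std::exp(-gtot * dt / C);
      gE_rec[i] *= decay;
      gI_rec[i] *= decay;
    }

    // integrate interneurons, threshold-and-reset
    for (int i = 0; i < n_inh; ++i) {
      if (refr[i] > 0) {
        --refr[i];
        V_inh[i] = V_reset;
      } else {
        double gtot = gL + gE_inh[i] + gI_inh[i];
        double veq = (gL * EL + gE_inh[i] * E_exc + gI_inh[i] * E_inh) / gtot;
        V_inh[i] = veq + (V_inh[i] - veq) * std::exp(-gtot * dt / C);
        if (V_inh[i] >= V_th) {
          inh_spike_unit.push_back(i + 1);
          inh_spike_time.push_back((t + 1) * dt * 1e-3); // seconds
          V_inh[i] = V_reset;
          refr[i] = ref_steps;
          ring[(t + delay_steps) % delay_steps].push_back(i);
        }
      }
      gE_inh[i] *= decay;
      gI_inh[i] *= decay;
    }
  }

  return List::create(
    _["vm"] = vm,
    _["inh_spike_unit"] = wrap(inh_spike_unit),
    _["inh_spike_time"] = wrap(inh_spike_time));
}
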