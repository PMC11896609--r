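// Leaky-integrate-and-fire network core.
//
// Forward-Euler integration of C_i dV_i/dt = (V_{i,0} - V_i)/R_i + I_ext,i
// + sum_j W_ji I_j(t), with templated action potentials (piecewise-linear
// rise to ap_max then fall to ap_min over ap_duration) and single-
// exponential postsynaptic currents of unit amplitude delivered beginning
// the time step after the presynaptic spike. Units: mV, ms, pA, pF, GOhm,
// under which dV = dt * I / C needs no conversion factors.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List lif_simulate_cpp(const arma::mat& Wt,            // post x pre weights
                      const arma::vec& V0, const arma::vec& Vthr,
                      const arma::vec& ap_min, const arma::vec& ap_max,
                      const arma::ivec& ap_steps,     // template length, steps
                      const arma::vec& Cm, const arma::vec& Rm,
                      const arma::ivec& sched_step,   // 0-based, sorted
                      const arma::ivec& sched_neuron, // 0-based
                      const arma::vec& constant_current,
                      int n_steps, double dt, double tau_syn,
                      double kick_current, bool store_voltage) {
  const int n = V0.n_elem;
  const double decay = std::exp(-dt / tau_syn);
  const bool has_synapses = arma::any(arma::vectorise(Wt) != 0.0);

  arma::vec V = V0;                  // membrane voltage
  arma::vec Iout(n, arma::fill::zeros);   // output PSC per neuron
  arma::vec pending(n, arma::fill::zeros);
  arma::ivec phase(n, arma::fill::zeros); // 0 = subthreshold, else step in AP
  std::vector< std::vector<double> > spikes(n);

  arma::mat Vtrace;
  if (store_voltage) Vtrace.set_size(n_steps, n);

  std::size_t sched_pos = 0;
  const std::size_t n_sched = sched_step.n_elem;
  arma::vec kick(n, arma::fill::zeros);
  arma::vec syn_in(n, arma::fill::zeros);

  for (int t = 0; t < n_steps; ++t) {
    // PSC kernels: decay, then add unit pulses from spikes of step t-1
    Iout *= decay;
    Iout += pending;
    pending.zeros();

    if (has_synapses) {
      syn_in = Wt * Iout;
    }

    // scheduled ORN kicks for this step
    kick.zeros();
    while (sched_pos < n_sched && sched_step[sched_pos] == t) {
      kick[sched_neuron[sched_pos]] += kick_current;
      ++sched_pos;
    }

    for (int i = 0; i < n; ++i) {
      if (phase[i] > 0) {
        // follow the action-potential template
        const int dur = ap_steps[i];
        const int half = dur / 2;
        const int p = phase[i];
        if (p <= half) {
          V[i] = Vthr[i] + (ap_max[i] - Vthr[i]) *
                 static_cast<double>(p) / half;
        } else {
          V[i] = ap_max[i] + (ap_min[i] - ap_max[i]) *
                 static_cast<double>(p - half) / (dur - half);
        }
        if (++phase[i] > dur) {
          phase[i] = 0;
          V[i] = ap_min[i];
        }
      } else {
        const double Iin = constant_current[i] + kick[i] +
                           (has_synapses ? syn_in[i] : 0.0);
        V[i] += dt / Cm[i] * ((V0[i] - V[i]) / Rm[i] + Iin);
        if (!std::isfinite(V[i])) {
          stop("non-finite voltage for neuron %d at t = %.3f ms",
               i + 1, t * dt);
        }
        if (V[i] >= Vthr[i]) {
          spikes[i].push_back(t * dt);
          phase[i] = 1;
          V[i] = Vthr[i];
          pending[i] += 1.0;  // PSC starts next step
        }
      }
    }

    if (store_voltage) Vtrace.row(t) = V.t();
  }

  List sp(n);
  for (int i = 0; i < n; ++i) sp[i] = NumericVector(spikes[i].begin(),
                                                    spikes[i].end());
  List out = List::create(Named("spikes") = sp);
  if (store_voltage) out["voltage"] = Vtrace;
  return out;
}
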