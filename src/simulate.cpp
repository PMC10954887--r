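#include <Rcpp.h>
using namespace Rcpp;

// Forward-Euler integration of a pulse-coupled Izhikevich network.
//
//   dv/dt = 0.04 v^2 + 5 v + 140 - u + I_ext (+ I_syn in current_pulse mode)
//   du/dt = a (b v - u)
//   if v >= 30 mV: spike; v <- c, u <- u + d
//
// Spikes detected at step k are delivered to their targets at step k+1.
// In voltage_kick mode each delivered spike adds w directly to the target's
// membrane potential; in current_pulse mode the accumulated weight acts as a
// one-step synaptic current of magnitude (sum w)/dt, which under forward Euler
// contributes the same increment dt * (sum w)/dt = sum w.
//
// Adjacency is CSR over the global neuron index: adj_ptr has n+1 entries,
// adj_tgt/adj_w list targets and weights of neuron i in
// [adj_ptr[i], adj_ptr[i+1]).
//
// An optional one-off perturbation adds perturb_weight to the pending drive of
// each neuron in perturb_targets at step perturb_step (1-based step index;
// 0 disables it), i.e. it arrives exactly like one extra presynaptic spike.
//
// Returns spike ids (0-based), spike times (ms), recorded membrane potentials
// for the neurons in record_idx (matrix: samples x channels, taken every
// record_decim steps after reset handling, so no sample exceeds 30 mV), and
// the recording time axis.
// [[Rcpp::export]]
List simulate_izhikevich_cpp(NumericVector v0, NumericVector u0,
                             NumericVector a, NumericVector b,
                             NumericVector c, NumericVector d,
                             NumericVector i_ext,
                             IntegerVector adj_ptr, IntegerVector adj_tgt,
                             NumericVector adj_w,
                             double dt, int n_steps,
                             IntegerVector record_idx, int record_decim,
                             bool current_pulse,
                             int perturb_step, IntegerVector perturb_targets,
                             double perturb_weight) {
  const int n = v0.size();
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> u(u0.begin(), u0.end());
  std::vector<double> pending(n, 0.0), incoming(n, 0.0);

  std::vector<int> spike_id;
  std::vector<double> spike_t;
  spike_id.reserve(n_steps / 4);
  spike_t.reserve(n_steps / 4);

  const int n_rec = record_idx.size();
  const int n_samp = n_steps / record_decim;
  NumericMatrix vrec(n_samp, n_rec);
  NumericVector trec(n_samp);
  int samp = 0;

  for (int step = 1; step <= n_steps; ++step) {
    const double t = step * dt;
    if (step == perturb_step) {
      for (int j = 0; j < perturb_targets.size(); ++j)
        pending[perturb_targets[j]] += perturb_weight;
    }
    std::fill(incoming.begin(), incoming.end(), 0.0);
    for (int i = 0; i < n; ++i) {
      double vi = v[i], ui = u[i];
      double drive = i_ext[i];
      if (current_pulse) drive += pending[i] / dt;
      double vn = vi + dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + drive);
      if (!current_pulse) vn += pending[i];
      double un = ui + dt * (a[i] * (b[i] * vi - ui));
      if (vn >= 30.0) {
        spike_id.push_back(i);
        spike_t.push_back(t);
        vn = c[i];
        un += d[i];
        for (int e = adj_ptr[i]; e < adj_ptr[i + 1]; ++e)
          incoming[adj_tgt[e]] += adj_w[e];
      }
      v[i] = vn;
      u[i] = un;
    }
    std::swap(pending, incoming);
    if (step % record_decim == 0 && samp < n_samp) {
      for (int j = 0; j < n_rec; ++j) vrec(samp, j) = v[record_idx[j]];
      trec[samp] = t;
      ++samp;
    }
    if (step % 1000 == 0) {
      for (int i = 0; i < n; ++i) {
        if (!std::isfinite(v[i]) || !std::isfinite(u[i]))
          stop("non-finite state at t = %f ms, neuron %d", t, i);
      }
    }
  }

  return List::create(_["spike_id"] = wrap(spike_id),
                      _["spike_time"] = wrap(spike_t),
                      _["v"] = vrec, _["time_ms"] = trec);
}
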