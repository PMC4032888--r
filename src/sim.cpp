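#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Clock-driven LIF integration with exact exponential propagators.
//
// State per neuron: membrane potential v and synaptic trace s. Between
// events they obey dv/dt = -v/tau_m + (1/tau_s - 1/tau_m) s, ds/dt = -s/tau_s,
// whose exact one-step map is v <- a v + (a - b) s, s <- b s with
// a = exp(-dt/tau_m), b = exp(-dt/tau_s). An impulse of weight J delivered to
// the trace therefore contributes exactly J * (exp(-t/tau_m) - exp(-t/tau_s))
// to v at every later step boundary.
//
// Event ordering within step k (covering [k dt, (k+1) dt]):
//   1. deliver recurrent spikes emitted in step k-1, external test impulses
//      scheduled at step k, and this step's noise events (all added to s);
//   2. propagate (v, s) over dt;
//   3. threshold check: v >= theta emits a spike stamped (k+1) dt and resets
//      v = s = 0, discarding all prior input to that neuron.
//
// Short-term synaptic depression is carried as a per-presynaptic-neuron
// factor r_j (outgoing column scale): r_j relaxes to 1 with time constant
// tau_r and is multiplied by f_stsd when j fires; transmission of a spike
// uses the factor in force at the moment of firing, before its own
// depression.
//
// The weight matrix arrives in CSC form (Wp, Wi, Wx): column j holds the
// outgoing connections of presynaptic neuron j, row indices are the
// postsynaptic targets.

// [[Rcpp::export]]
List sim_lif_cpp(IntegerVector Wp, IntegerVector Wi, NumericVector Wx, int N,
                 NumericVector sigma, double tau_m, double tau_s, double theta,
                 double rho, double dt, double t_total, double t_transient,
                 double max_spikes,
                 bool stsd, double tau_r, double f_stsd,
                 IntegerVector ev_step, IntegerVector ev_neuron,
                 NumericVector ev_amp, bool record_v) {
  const int n_steps = (int) std::lround(t_total / dt);
  const double a = std::exp(-dt / tau_m);
  const double b = std::exp(-dt / tau_s);
  const double er = stsd ? std::exp(-dt / tau_r) : 1.0;
  const double noise_lambda = (double) N * rho * dt;

  std::vector<double> v(N, 0.0), s(N, 0.0), r(N, 1.0);
  std::vector<int> pending;            // neurons that spiked last step
  std::vector<double> pending_fac;     // transmission factor for each
  std::vector<double> sp_time;
  std::vector<int> sp_id;
  sp_time.reserve(1 << 16);
  sp_id.reserve(1 << 16);

  NumericMatrix vtrace = record_v ? NumericMatrix(n_steps + 1, N)
                                  : NumericMatrix(0, 0);

  bool any_sigma = false;
  for (int i = 0; i < N; ++i) if (sigma[i] > 0) { any_sigma = true; break; }

  long long counted = 0;               // spikes after the transient
  double t_end = t_total;
  int ev_ptr = 0;
  const int n_ev = ev_step.size();
  bool aborted = false;

  for (int k = 0; k < n_steps; ++k) {
    // 1a. recurrent deliveries from last step's spikes
    for (size_t m = 0; m < pending.size(); ++m) {
      const int j = pending[m];
      const double fac = pending_fac[m];
      for (int idx = Wp[j]; idx < Wp[j + 1]; ++idx)
        s[Wi[idx]] += Wx[idx] * fac;
    }
    pending.clear();
    pending_fac.clear();

    // 1b. external test impulses scheduled at this step boundary
    while (ev_ptr < n_ev && ev_step[ev_ptr] == k) {
      s[ev_neuron[ev_ptr]] += ev_amp[ev_ptr];
      ++ev_ptr;
    }

    // 1c. noise events: network-total count is Poisson(N rho dt); each event
    // hits a uniformly random neuron with a Gaussian amplitude of that
    // neuron's sigma. Equivalent to independent Poisson(rho dt) per neuron.
    if (any_sigma && noise_lambda > 0) {
      const int n_noise = (int) R::rpois(noise_lambda);
      for (int m = 0; m < n_noise; ++m) {
        int u = (int) (unif_rand() * N);
        if (u >= N) u = N - 1;
        s[u] += sigma[u] * norm_rand();
      }
    }

    // 2. exact propagation over dt
    for (int i = 0; i < N; ++i) {
      v[i] = a * v[i] + (a - b) * s[i];
      s[i] *= b;
    }
    if (stsd)
      for (int j = 0; j < N; ++j) r[j] = 1.0 + (r[j] - 1.0) * er;

    if (record_v)
      for (int i = 0; i < N; ++i) vtrace(k + 1, i) = v[i];

    // 3. threshold crossings, stamped at the end of the step
    const double t_now = (k + 1) * dt;
    for (int i = 0; i < N; ++i) {
      if (v[i] >= theta) {
        sp_time.push_back(t_now);
        sp_id.push_back(i);
        v[i] = 0.0;
        s[i] = 0.0;
        pending.push_back(i);
        if (stsd) {
          pending_fac.push_back(r[i]);
          r[i] *= f_stsd;
        } else {
          pending_fac.push_back(1.0);
        }
        if (t_now > t_transient) ++counted;
      }
    }

    if ((k & 1023) == 0) {
      for (int i = 0; i < N; ++i)
        if (!std::isfinite(v[i])) {
          aborted = true;
          break;
        }
      if (aborted) {
        t_end = t_now;
        break;
      }
      Rcpp::checkUserInterrupt();
    }

    if (max_spikes > 0 && counted >= (long long) max_spikes) {
      t_end = t_now;
      break;
    }
  }

  if (aborted)
    stop("membrane potential diverged (non-finite state) at t = %f ms", t_end);

  List out = List::create(
      _["times"] = NumericVector(sp_time.begin(), sp_time.end()),
      _["ids"] = IntegerVector(sp_id.begin(), sp_id.end()),
      _["t_end"] = t_end);
  if (record_v) out["v_trace"] = vtrace;
  return out;
}
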