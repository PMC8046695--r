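// Core simulation engine: Izhikevich neurons, additive all-to-all STDP with a
// finite pairing window, exponential current/weight decay, and seeded uniform
// noise drive.  All heavy per-millisecond loops live here; the R layer owns
// configuration, protocols and analysis.
#include <Rcpp.h>
#include <deque>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Counter-free splitmix64 streams: one independent, reproducible stream per
// (seed, stream id).  Uniforms are built from the top 53 bits so draws are
// identical on every platform regardless of compiler library details.
// ---------------------------------------------------------------------------
static inline uint64_t sm64_next(uint64_t &s) {
  uint64_t z = (s += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

// Scatter (seed, stream) through the splitmix64 finalizer so that distinct
// streams start at unrelated counter positions; a plain additive offset
// would make streams shifted copies of one another.
static inline uint64_t mix64(uint64_t z) {
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t stream_state(uint64_t seed, uint64_t stream) {
  return mix64(seed * 0x9E3779B97F4A7C15ULL + 0xD1B54A32D192ED03ULL) ^
         mix64((stream + 1ULL) * 0x8CB92BA72F3D8DD7ULL);
}

static inline double sm64_unif(uint64_t &s) {
  return (sm64_next(s) >> 11) * (1.0 / 9007199254740992.0);
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_unif_stream(double seed, double stream, int n) {
  uint64_t s = stream_state((uint64_t)seed, (uint64_t)stream);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = sm64_unif(s);
  return out;
}

// Repeated one-step exponential decay, for step-count-exact decay checks.
// The per-step factor and the accumulator carry extended precision so that
// a million repeated one-step decays still match exp(-t/tau) to ~1e-13.
// [[Rcpp::export]]
double cpp_decay_n(double x, double tau_ms, double n_steps) {
  const long double f = expl(-1.0L / (long double)tau_ms);
  long double acc = x;
  const double n = n_steps;
  for (double i = 0; i < n; i += 1.0) acc *= f;
  return (double)acc;
}

struct NeuronC {
  double v, u;
};

struct SynC {
  int pre, post;          // 0-based input / output index
  double g, I;
  long double dec_g;      // per-ms weight decay factor (extended precision)
  std::deque<int> pre_buf, post_buf;
};

static inline bool step_neuron_c(NeuronC &n, double a, double b, double c,
                                 double d, double vpeak, double I) {
  const double dv = 0.04 * n.v * n.v + 5.0 * n.v + 140.0 - n.u + I;
  const double du = a * (b * n.v - n.u);
  n.v += dv;
  n.u += du;
  if (!std::isfinite(n.v) || !std::isfinite(n.u))
    stop("neuron state became non-finite (divergent configuration)");
  if (n.v >= vpeak) {
    n.v = c;
    n.u += d;
    return true;
  }
  return false;
}

static inline double clampg(double g, double lo, double hi) {
  return g < lo ? lo : (g > hi ? hi : g);
}

// STDP pairing sums over a spike buffer.  dt_sign=+1: LTP side (t - t_buf),
// dt_sign=-1: LTD side (t_buf - t).  Lag 0 contributes nothing; lag == window
// is included, older spikes are evicted before summing.
static inline double pair_sum(std::deque<int> &buf, int t, int window,
                              double amp_p, double tau_p, double amp_m,
                              double tau_m, bool ltp) {
  while (!buf.empty() && buf.front() < t - window) buf.pop_front();
  double s = 0.0;
  for (size_t i = 0; i < buf.size(); ++i) {
    const int lag = t - buf[i];  // >= 0 by construction
    if (lag == 0) continue;
    s += ltp ? amp_p * std::exp(-lag / tau_p) : amp_m * std::exp(-lag / tau_m);
  }
  return s;
}

// ---------------------------------------------------------------------------
// Full staged network simulation.
//
// Per 1-ms step: (1) draw drive currents for active inputs (inputs in index
// order, one fresh uniform each); (2) step input neurons; (3) for each input
// spike, apply the LTD pairing and deliver current on its outgoing synapses;
// (4) step output neurons with g_scale * (sum of incoming synaptic currents);
// (5) for each output spike, apply the LTP pairing on its incoming synapses;
// (6) exponential decay of all synaptic currents and weights.
//
// A stage either has a fixed duration (stage_dur_ms > 0) or terminates when
// every listed contralateral weight exceeds (1 + margin) times its ipsilateral
// competitor (stage_dur_ms < 0), subject to a hard cap.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate_network(NumericVector nrn, NumericVector ker,
                          double tau_scd_ms, double eta, double g_scale,
                          double g_min, double g_max, IntegerVector syn_pre,
                          IntegerVector syn_post, NumericVector g0,
                          NumericVector tau_swd_ms, int n_in, int n_out,
                          IntegerMatrix stage_active,
                          NumericVector stage_dur_ms,
                          IntegerVector pred_contra, IntegerVector pred_ipsi,
                          double pred_margin, double pred_cap_ms, double i_lo,
                          double i_hi, double seed, int record_every_ms,
                          bool record_spikes) {
  const double a = nrn[0], b = nrn[1], c = nrn[2], d = nrn[3], vpeak = nrn[4];
  const double a_plus = ker[0], a_minus = ker[1], tau_plus = ker[2],
               tau_minus = ker[3];
  const int window = (int)ker[4];
  const double dec_I = std::exp(-1.0 / tau_scd_ms);
  const int n_syn = syn_pre.size();
  const int n_stage = stage_active.nrow();
  const int n_nrn = n_in + n_out;

  // resting state: stable root of 0.04 v^2 + (5-b) v + 140 = 0, u = b v
  const double disc = (5.0 - b) * (5.0 - b) - 0.16 * 140.0;
  double v0 = -70.0;
  if (disc >= 0.0) v0 = (-(5.0 - b) - std::sqrt(disc)) / 0.08;
  std::vector<NeuronC> neurons(n_nrn);
  for (int i = 0; i < n_nrn; ++i) neurons[i] = NeuronC{v0, b * v0};

  std::vector<SynC> syn(n_syn);
  for (int s = 0; s < n_syn; ++s) {
    syn[s].pre = syn_pre[s];
    syn[s].post = syn_post[s];
    syn[s].g = g0[s];
    syn[s].I = 0.0;
    syn[s].dec_g = expl(-1.0L / (long double)tau_swd_ms[s]);
  }
  // incoming synapse lists per output
  std::vector<std::vector<int>> incoming(n_out), outgoing(n_in);
  for (int s = 0; s < n_syn; ++s) {
    outgoing[syn[s].pre].push_back(s);
    incoming[syn[s].post].push_back(s);
  }

  // sizing for the record buffers
  double total_cap = 0.0;
  for (int k = 0; k < n_stage; ++k)
    total_cap += (stage_dur_ms[k] > 0) ? stage_dur_ms[k] : pred_cap_ms;
  const R_xlen_t max_rec =
      (R_xlen_t)(total_cap / record_every_ms) + 2 * n_stage + 4;
  std::vector<double> rec_t;
  std::vector<int> rec_stage;
  std::vector<double> rec_w;
  rec_t.reserve(max_rec);
  rec_stage.reserve(max_rec);
  rec_w.reserve(max_rec * n_syn);

  std::vector<std::vector<double>> spikes(record_spikes ? n_nrn : 0);
  IntegerMatrix spike_counts(n_stage, n_nrn);
  NumericVector stage_start(n_stage), stage_end(n_stage);
  LogicalVector pred_met(n_stage);

  std::vector<uint64_t> rng(n_in);
  std::vector<double> Iin(n_in);
  std::vector<bool> in_spiked(n_in), out_spiked(n_out);

  long long t = 0;  // global time in ms
  for (int k = 0; k < n_stage; ++k) {
    stage_start[k] = (double)t;
    const bool by_pred = !(stage_dur_ms[k] > 0);
    const long long t_stop =
        t + (long long)(by_pred ? pred_cap_ms : stage_dur_ms[k]);
    for (int i = 0; i < n_in; ++i)
      rng[i] = stream_state((uint64_t)seed, (uint64_t)(k * 256 + i));
    bool done = false;
    while (!done && t < t_stop) {
      // (1) drive
      for (int i = 0; i < n_in; ++i) {
        if (stage_active(k, i)) {
          Iin[i] = i_lo + (i_hi - i_lo) * sm64_unif(rng[i]);
        } else {
          Iin[i] = 0.0;
        }
      }
      // (2) input neurons
      for (int i = 0; i < n_in; ++i) {
        in_spiked[i] = step_neuron_c(neurons[i], a, b, c, d, vpeak, Iin[i]);
        if (in_spiked[i]) {
          spike_counts(k, i)++;
          if (record_spikes) spikes[i].push_back((double)t);
        }
      }
      // (3) presynaptic events
      for (int i = 0; i < n_in; ++i) {
        if (!in_spiked[i]) continue;
        for (int si : outgoing[i]) {
          SynC &sy = syn[si];
          const double s_ltd = pair_sum(sy.post_buf, (int)t,
                                        window, a_plus, tau_plus, a_minus,
                                        tau_minus, false);
          sy.g = clampg(sy.g + eta * s_ltd, g_min, g_max);
          sy.I += sy.g;
          sy.pre_buf.push_back((int)t);
        }
      }
      // (4) output neurons
      for (int o = 0; o < n_out; ++o) {
        double Io = 0.0;
        for (int si : incoming[o]) Io += syn[si].I;
        out_spiked[o] =
            step_neuron_c(neurons[n_in + o], a, b, c, d, vpeak, g_scale * Io);
        if (out_spiked[o]) {
          spike_counts(k, n_in + o)++;
          if (record_spikes) spikes[n_in + o].push_back((double)t);
        }
      }
      // (5) postsynaptic events
      for (int o = 0; o < n_out; ++o) {
        if (!out_spiked[o]) continue;
        for (int si : incoming[o]) {
          SynC &sy = syn[si];
          const double s_ltp = pair_sum(sy.pre_buf, (int)t,
                                        window, a_plus, tau_plus, a_minus,
                                        tau_minus, true);
          sy.g = clampg(sy.g + eta * s_ltp, g_min, g_max);
          sy.post_buf.push_back((int)t);
        }
      }
      // (6) decay
      for (int s = 0; s < n_syn; ++s) {
        syn[s].I *= dec_I;
        syn[s].g = (double)((long double)syn[s].g * syn[s].dec_g);
        if (syn[s].g < g_min) syn[s].g = g_min;
      }
      // record
      if (t % record_every_ms == 0) {
        rec_t.push_back((double)t);
        rec_stage.push_back(k + 1);
        for (int s = 0; s < n_syn; ++s) rec_w.push_back(syn[s].g);
      }
      ++t;
      // predicate check (after the completed step)
      if (by_pred) {
        bool ok = pred_contra.size() > 0;
        for (int j = 0; j < pred_contra.size(); ++j) {
          const double gc = syn[pred_contra[j] - 1].g;
          const double gi = syn[pred_ipsi[j] - 1].g;
          if (!(gc > (1.0 + pred_margin) * gi)) {
            ok = false;
            break;
          }
        }
        if (ok) done = true;
      }
      if ((t & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
    }
    pred_met[k] = by_pred && done;
    stage_end[k] = (double)t;
    // stage-end snapshot
    rec_t.push_back((double)t);
    rec_stage.push_back(k + 1);
    for (int s = 0; s < n_syn; ++s) rec_w.push_back(syn[s].g);
  }

  const R_xlen_t nr = (R_xlen_t)rec_t.size();
  NumericMatrix W(nr, n_syn);
  for (R_xlen_t r = 0; r < nr; ++r)
    for (int s = 0; s < n_syn; ++s) W(r, s) = rec_w[r * n_syn + s];
  NumericVector g_final(n_syn);
  for (int s = 0; s < n_syn; ++s) g_final[s] = syn[s].g;

  List spk = R_NilValue;
  if (record_spikes) {
    List tmp(n_nrn);
    for (int i = 0; i < n_nrn; ++i) tmp[i] = wrap(spikes[i]);
    spk = tmp;
  }
  return List::create(
      _["time_ms"] = wrap(rec_t), _["stage"] = wrap(rec_stage), _["W"] = W,
      _["g_final"] = g_final, _["stage_start_ms"] = stage_start,
      _["stage_end_ms"] = stage_end, _["spike_counts"] = spike_counts,
      _["spikes"] = spk, _["pred_met"] = pred_met);
}
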