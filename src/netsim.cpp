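#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Directed Erdos-Renyi connectivity in CSR form (out-lists).
// Row j holds the postsynaptic targets of presynaptic neuron j, no self-edges.
// Uses R's RNG so results are governed by set.seed() on the R side.
// [[Rcpp::export(name = ".cpp_build_connectivity")]]
List cpp_build_connectivity(int N, double p) {
  std::vector<int> targets;
  targets.reserve(static_cast<size_t>(p * N * (double)N * 1.05) + 64);
  IntegerVector offsets(N + 1);
  if (p >= 1.0) {
    for (int j = 0; j < N; ++j) {
      offsets[j + 1] = offsets[j] + (N - 1);
      for (int i = 0; i < N; ++i) if (i != j) targets.push_back(i);
    }
  } else {
    for (int j = 0; j < N; ++j) {
      int deg = 0;
      for (int i = 0; i < N; ++i) {
        if (i == j) continue;
        if (unif_rand() < p) { targets.push_back(i); ++deg; }
      }
      offsets[j + 1] = offsets[j] + deg;
    }
  }
  return List::create(_["offsets"] = offsets,
                      _["targets0"] = IntegerVector(targets.begin(), targets.end()));
}

// Leaky integrate-and-fire E-I network with bi-exponential synaptic filtering.
//
// Per-neuron synaptic state is two weighted exponential pairs (A, B): an
// impulse of weight J at time t0 contributes J*[exp(-(t-t0)/tau_d) -
// exp(-(t-t0)/tau_r)]/(tau_d - tau_r), so A accumulates J with decay tau_d and
// B with decay tau_r; the drive is (A - B)/(tau_d - tau_r). Between events the
// pair is advanced exactly by precomputed decay factors, O(N) per step.
//
// Integration: Heun (2nd order) on smooth segments; threshold crossings are
// detected at step end, the crossing time is linearly interpolated inside the
// step, and the neuron is clamped at V_reset until t_spike + t_ref with a
// partial Heun step when refractoriness ends mid-step. Recurrent spikes are
// delivered at the end-of-step boundary (zero transmission delay).
// [[Rcpp::export(name = ".cpp_simulate_network")]]
List cpp_simulate_network(IntegerVector offsets, IntegerVector targets0,
                          int N, int NE,
                          double p_unused,
                          double J_EO, double J_IO, double J_EE, double J_IE,
                          double J_EI, double J_II,
                          double V_rest_E, double V_rest_I, double V_th, double V_reset,
                          double tau_m_E, double tau_m_I,
                          double tau_r, double tau_d_E, double tau_d_I,
                          double t_ref_E, double t_ref_I,
                          double dt, double duration,
                          double n_o, double Q_o_perms,
                          NumericVector init_V,
                          double const_input,
                          IntegerVector record_idx0, double record_every_ms) {
  const int NI = N - NE;
  const long nsteps = (long)std::llround(duration / dt);
  const double dfE = std::exp(-dt / tau_d_E);
  const double dfI = std::exp(-dt / tau_d_I);
  const double dfR = std::exp(-dt / tau_r);
  const double denE = tau_d_E - tau_r;
  const double denI = tau_d_I - tau_r;
  const double muE = NE * n_o * Q_o_perms * dt;  // expected external events per step
  const double muI = NI * n_o * Q_o_perms * dt;

  std::vector<double> V(init_V.begin(), init_V.end());
  std::vector<double> AE(N, 0.0), BE(N, 0.0), AI(N, 0.0), BI(N, 0.0);
  std::vector<double> refr_until(N, -1.0);
  std::vector<int> spikers; spikers.reserve(256);
  std::vector<double> sp_time; sp_time.reserve(1 << 16);
  std::vector<int> sp_id; sp_id.reserve(1 << 16);

  const int n_rec = record_idx0.size();
  const int rec_every = (record_every_ms > 0 && n_rec > 0) ?
    (int)std::llround(record_every_ms / dt) : 0;
  const long n_samp = rec_every > 0 ? nsteps / rec_every : 0;
  NumericMatrix Vrec(n_rec > 0 ? n_rec : 1, n_rec > 0 ? n_samp : 1);
  NumericVector t_samp(n_rec > 0 ? n_samp : 0);
  long samp_k = 0;

  for (long step = 0; step < nsteps; ++step) {
    const double t = step * dt;
    const double t1 = t + dt;

    // external Poisson events arriving at time t (population-wide draw)
    if (muE > 0) {
      int KE = (int)R::rpois(muE);
      for (int k = 0; k < KE; ++k) {
        int i = (int)(unif_rand() * NE); if (i >= NE) i = NE - 1;
        AE[i] += J_EO; BE[i] += J_EO;
      }
      int KI = (int)R::rpois(muI);
      for (int k = 0; k < KI; ++k) {
        int i = NE + (int)(unif_rand() * NI); if (i >= N) i = N - 1;
        AE[i] += J_IO; BE[i] += J_IO;
      }
    }

    spikers.clear();
    for (int i = 0; i < N; ++i) {
      const bool isE = i < NE;
      const double tau_m = isE ? tau_m_E : tau_m_I;
      const double V_rest = isE ? V_rest_E : V_rest_I;

      // synaptic drive at t (states currently at time t)
      const double I0 = (AE[i] - BE[i]) / denE + (AI[i] - BI[i]) / denI + const_input;
      // decay states to t1
      AE[i] *= dfE; BE[i] *= dfR; AI[i] *= dfI; BI[i] *= dfR;
      const double I1 = (AE[i] - BE[i]) / denE + (AI[i] - BI[i]) / denI + const_input;

      if (refr_until[i] >= t1 - 1e-12) { V[i] = V_reset; continue; }

      double t_from = t, V0 = V[i], Ia = I0;
      if (refr_until[i] > t) {
        // refractoriness ends inside this step: partial Heun from its end
        t_from = refr_until[i];
        V0 = V_reset;
        const double back = t1 - t_from;  // states at t1; rewind to t_from
        Ia = (AE[i] * std::exp(back / tau_d_E) - BE[i] * std::exp(back / tau_r)) / denE
           + (AI[i] * std::exp(back / tau_d_I) - BI[i] * std::exp(back / tau_r)) / denI
           + const_input;
      }
      const double h = t1 - t_from;
      const double k1 = (V_rest - V0) / tau_m + Ia;
      const double Vp = V0 + h * k1;
      const double k2 = (V_rest - Vp) / tau_m + I1;
      double Vn = V0 + 0.5 * h * (k1 + k2);

      if (Vn >= V_th) {
        const double frac = (V_th - V0) / (Vn - V0);
        const double ts = t_from + h * (frac > 0 ? (frac < 1 ? frac : 1) : 0);
        sp_time.push_back(ts);
        sp_id.push_back(i + 1);
        spikers.push_back(i);
        refr_until[i] = ts + (isE ? t_ref_E : t_ref_I);
        Vn = V_reset;
      }
      if (Vn > 1e3 || Vn < -1e3)
        stop("membrane potential blew up (|V| > 1000 mV); reduce dt (currently %f ms)", dt);
      V[i] = Vn;
    }

    // recurrent delivery at the t1 boundary (states are at t1)
    for (size_t s = 0; s < spikers.size(); ++s) {
      const int j = spikers[s];
      const bool jE = j < NE;
      for (int k = offsets[j]; k < offsets[j + 1]; ++k) {
        const int i = targets0[k];
        if (jE) {
          const double w = (i < NE) ? J_EE : J_IE;
          AE[i] += w; BE[i] += w;
        } else {
          const double w = (i < NE) ? J_EI : J_II;
          AI[i] += w; BI[i] += w;
        }
      }
    }

    if (rec_every > 0 && ((step + 1) % rec_every == 0) && samp_k < n_samp) {
      for (int r = 0; r < n_rec; ++r) Vrec(r, samp_k) = V[record_idx0[r]];
      t_samp[samp_k] = t1;
      ++samp_k;
    }
    if ((step & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["time"] = NumericVector(sp_time.begin(), sp_time.end()),
    _["id"] = IntegerVector(sp_id.begin(), sp_id.end()),
    _["V"] = (n_rec > 0 ? Vrec : NumericMatrix(0, 0)),
    _["t_samp"] = t_samp);
}
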