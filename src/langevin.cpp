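#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Demographic-noise Langevin normal form near a supercritical Hopf point:
//   dX = (a X - X^3 + h) dt + sqrt(max(X, 0)) dW,   X(0) = eps.
// An avalanche ends at the first passage X <= 0; duration T is the elapsed
// time and size S the trapezoid integral of X over [0, T]. Negative
// excursions within a step are absorbed (not reflected).
// [[Rcpp::export(name = ".cpp_simulate_normal_form")]]
List cpp_simulate_normal_form(double a, double h, double eps, double dt,
                              int n_avalanches, double max_steps) {
  NumericVector T(n_avalanches), S(n_avalanches);
  LogicalVector capped(n_avalanches);
  const double sdt = std::sqrt(dt);
  for (int k = 0; k < n_avalanches; ++k) {
    double X = eps, area = 0.0;
    double steps = 0;
    bool hit_cap = false;
    for (;;) {
      if (steps >= max_steps) { hit_cap = true; break; }
      const double noise = std::sqrt(X > 0 ? X : 0.0) * sdt * norm_rand();
      double Xn = X + (a * X - X * X * X + h) * dt + noise;
      steps += 1;
      if (Xn <= 0) { area += 0.5 * X * dt; X = Xn; break; }
      area += 0.5 * (X + Xn) * dt;
      X = Xn;
    }
    T[k] = steps * dt;
    S[k] = area;
    capped[k] = hit_cap;
    if ((k & 0xFF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["T"] = T, _["S"] = S, _["capped"] = capped);
}
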