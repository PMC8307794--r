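// Fixed-step classical RK4 integration of the two-compartment absorption
// cascade.  State: stomach monosaccharide, stomach starch, gut starch, gut
// glucose.  Emits the absorption rate k_abs * Q on the step grid and stops
// once the running trapezoid integral of that rate reaches `target` grams.

#include <Rcpp.h>
#include <vector>

namespace {
struct State { double sm, ss, qs, q; };

inline State deriv(const State &s, double ke, double kd, double ka) {
  return {-ke * s.sm, -ke * s.ss, ke * s.ss - kd * s.qs,
          ke * s.sm + kd * s.qs - ka * s.q};
}

inline State axpy(const State &s, double h, const State &d) {
  return {s.sm + h * d.sm, s.ss + h * d.ss, s.qs + h * d.qs, s.q + h * d.q};
}
}  // namespace

// [[Rcpp::export]]
Rcpp::NumericVector absorption_rk4_cpp(double mono, double starch, double ke,
                                       double kd, double ka, double h,
                                       int n_steps, double target) {
  State s{mono, starch, 0.0, 0.0};
  std::vector<double> rates;
  rates.reserve(n_steps + 1);
  rates.push_back(ka * s.q);
  double absorbed = 0.0;
  for (int i = 1; i <= n_steps; ++i) {
    const State k1 = deriv(s, ke, kd, ka);
    const State k2 = deriv(axpy(s, h / 2, k1), ke, kd, ka);
    const State k3 = deriv(axpy(s, h / 2, k2), ke, kd, ka);
    const State k4 = deriv(axpy(s, h, k3), ke, kd, ka);
    s.sm += (h / 6) * (k1.sm + 2 * k2.sm + 2 * k3.sm + k4.sm);
    s.ss += (h / 6) * (k1.ss + 2 * k2.ss + 2 * k3.ss + k4.ss);
    s.qs += (h / 6) * (k1.qs + 2 * k2.qs + 2 * k3.qs + k4.qs);
    s.q  += (h / 6) * (k1.q  + 2 * k2.q  + 2 * k3.q  + k4.q);
    const double r = ka * s.q;
    absorbed += h * (rates.back() + r) / 2;
    rates.push_back(r);
    if (absorbed >= target) break;
  }
  return Rcpp::NumericVector(rates.begin(), rates.end());
}
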