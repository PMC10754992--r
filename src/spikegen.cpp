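// Renewal / thinning spike-train sampler used by the phenomenological
// generator. Draws come from R's RNG so set.seed() on the R side fixes the
// realization. Gap structure: refractory + Exp(lambda0 * (1 + mod)), with
// candidate thinning against the beta-modulated hazard, which keeps the
// long-run mean rate at the nominal value for mod = 0.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
NumericVector cpp_sim_train(double rate_hz, double mod_depth, double beta_freq,
                            double phase, double refractory, double duration) {
  std::vector<double> times;
  const double r = rate_hz / 1000.0;            // spikes per ms
  if (r <= 0.0) return NumericVector(0);
  if (1.0 / r <= refractory)
    stop("firing rate incompatible with refractory period");
  const double lambda0 = 1.0 / (1.0 / r - refractory);
  const double lam_cand = lambda0 * (1.0 + mod_depth);
  const double two_pi_f = 2.0 * M_PI * beta_freq / 1000.0;
  RNGScope scope;
  double t = 0.0;
  for (;;) {
    t += R::exp_rand() / lam_cand;
    if (t > duration) break;
    const double acc =
      (1.0 + mod_depth * std::sin(two_pi_f * t + phase)) / (1.0 + mod_depth);
    if (R::unif_rand() <= acc) {
      times.push_back(t);
      t += refractory;
    }
  }
  return NumericVector(times.begin(), times.end());
}
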