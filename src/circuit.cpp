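// Fixed-step integrator for the reduced cortico-basal-ganglia-thalamus
// spiking network. Izhikevich single-compartment neurons; synapses are
// signed exponential-decay current kicks with a fixed axonal delay per edge.
// All stochasticity (the membrane noise current) is drawn from R's RNG so a
// set.seed() on the R side makes runs exactly reproducible.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
List cpp_simulate_izh(const arma::vec& a, const arma::vec& b,
                      const arma::vec& c, const arma::vec& d,
                      const arma::vec& I0, const arma::vec& noise_sd,
                      const arma::ivec& e_src, const arma::ivec& e_dst,
                      const arma::vec& e_w, const arma::ivec& e_delay,
                      double dt, int n_steps,
                      double tau_exc, double tau_inh) {
  const int n = a.n_elem;
  const int ne = e_src.n_elem;

  // CSR adjacency over source neuron
  std::vector<std::vector<int>> out_edges(n);
  for (int e = 0; e < ne; ++e) out_edges[e_src[e]].push_back(e);

  int max_delay = 0;
  for (int e = 0; e < ne; ++e) if (e_delay[e] > max_delay) max_delay = e_delay[e];
  const int ring_len = max_delay + 1;
  // pending synaptic increments: ring slot x neuron, split by sign
  arma::mat ring_exc(ring_len, n, arma::fill::zeros);
  arma::mat ring_inh(ring_len, n, arma::fill::zeros);

  arma::vec v = c;                 // start at rest
  arma::vec u = b % v;
  arma::vec s_exc(n, arma::fill::zeros), s_inh(n, arma::fill::zeros);
  const double dec_e = std::exp(-dt / tau_exc);
  const double dec_i = std::exp(-dt / tau_inh);
  const double noise_scale = 1.0 / std::sqrt(dt);

  std::vector<std::vector<double>> spikes(n);
  RNGScope scope;

  for (int step = 0; step < n_steps; ++step) {
    const int slot = step % ring_len;
    s_exc = s_exc * dec_e + ring_exc.row(slot).t();
    s_inh = s_inh * dec_i + ring_inh.row(slot).t();
    ring_exc.row(slot).zeros();
    ring_inh.row(slot).zeros();

    for (int i = 0; i < n; ++i) {
      double In = I0[i] + s_exc[i] - s_inh[i];
      if (noise_sd[i] > 0.0) In += noise_sd[i] * noise_scale * R::norm_rand();
      // two half-steps on v for stability at dt = 0.1 ms
      double vi = v[i], ui = u[i];
      vi += 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + In);
      vi += 0.5 * dt * (0.04 * vi * vi + 5.0 * vi + 140.0 - ui + In);
      ui += dt * a[i] * (b[i] * vi - ui);
      if (!std::isfinite(vi) || !std::isfinite(ui))
        stop("numerical blow-up at t = %.2f ms, neuron %d", (step + 1) * dt, i + 1);
      if (vi >= 30.0) {
        const double t_spk = (step + 1) * dt;
        spikes[i].push_back(t_spk);
        vi = c[i];
        ui += d[i];
        for (int e : out_edges[i]) {
          const int dst = e_dst[e];
          const int at = (step + e_delay[e]) % ring_len;
          const double w = e_w[e];
          if (w >= 0.0) ring_exc(at, dst) += w; else ring_inh(at, dst) -= w;
        }
      }
      v[i] = vi; u[i] = ui;
    }
  }

  List out(n);
  for (int i = 0; i < n; ++i) out[i] = NumericVector(spikes[i].begin(), spikes[i].end());
  return out;
}
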