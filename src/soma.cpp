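#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Euler integration of the two-variable quadratic (Izhikevich-type) soma:
//   C dv/dt = k (v - v_rest)(v - v_thresh) - u + I
//   du/dt   = a (b (v - v_rest) - u)
// with spike emission when v >= v_peak followed by the reset v <- c,
// u <- u + d.  I is supplied sampled at interval dt_in (seconds) and is
// linearly interpolated onto the integration step dt.  Currents in pA.
// The spike time is recorded as the time at the start of the step on which
// the threshold crossing is detected.
// [[Rcpp::export]]
Rcpp::List izhikevich_cpp(const arma::vec& I_pA,
                          const double dt_in,
                          const double dt,
                          const double C,
                          const double k,
                          const double v_rest,
                          const double v_thresh,
                          const double v_peak,
                          const double a,
                          const double b,
                          const double c,
                          const double d,
                          const double v0,
                          const double u0,
                          const bool record_v) {
  const double duration = (I_pA.n_elem - 1) * dt_in;
  const int n_steps = (int) std::floor(duration / dt + 0.5);
  double v = v0, u = u0;
  std::vector<double> spikes;
  vec vtrace;
  if (record_v) vtrace.set_size(n_steps);

  for (int i = 0; i < n_steps; i++) {
    const double t = i * dt;
    // linear interpolation of the input current
    const double x = t / dt_in;
    const uword j = std::min((uword) x, (uword) (I_pA.n_elem - 2));
    const double frac = x - j;
    const double I = I_pA(j) * (1.0 - frac) + I_pA(j + 1) * frac;

    if (record_v) vtrace(i) = v;
    const double dv = (k * (v - v_rest) * (v - v_thresh) - u + I) / C;
    const double du = a * (b * (v - v_rest) - u);
    v += dt * dv * 1e3;  // dt in s, rates per ms below
    u += dt * du * 1e3;
    if (v >= v_peak) {
      spikes.push_back(t);
      v = c;
      u += d;
    }
  }
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("spike_times") = spikes,
      Rcpp::Named("v_final") = v,
      Rcpp::Named("u_final") = u);
  if (record_v) out["v"] = vtrace;
  return out;
}

// Leaky integrate-and-fire motor-neuron pool with stochastic membrane
// resets.  input is an (n_mn x T) matrix of afferent drive sampled at dt
// (already weighted, post-synaptically filtered and scaled);
//   tau_j dV_j/dt = -g_j (V_j - E_j) + input_j(t)
// On V_j >= threshold a spike is emitted and V_j <- E_j + N(0, reset_sd).
// Uses the R RNG so results honour set.seed().
// [[Rcpp::export]]
Rcpp::List lif_pool_cpp(const arma::mat& input,
                        const double dt,
                        const arma::vec& E,
                        const arma::vec& g,
                        const arma::vec& tau_s,
                        const double threshold,
                        const double reset_sd) {
  const uword n = input.n_rows;
  const uword T = input.n_cols;
  vec V = E;
  std::vector< std::vector<double> > spikes(n);
  for (uword t = 0; t < T; t++) {
    for (uword j = 0; j < n; j++) {
      V(j) += dt / tau_s(j) * (-g(j) * (V(j) - E(j)) + input(j, t));
      if (V(j) >= threshold) {
        spikes[j].push_back(t * dt);
        V(j) = E(j) + R::rnorm(0.0, reset_sd);
      }
    }
  }
  Rcpp::List out(n);
  for (uword j = 0; j < n; j++) out[j] = spikes[j];
  return out;
}
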