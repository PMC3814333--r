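#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Advance a sheet of spatially coupled phase oscillators and optionally
// record, at a fixed sampling interval, (i) the sum of exp(i*theta) over the
// sheet (whose real part is the un-normalised LFP), (ii) Gabor-filtered
// cosine-phase fields evaluated at a set of grid positions (the phase-only
// dendritic currents), and (iii) the full phase grid.
//
// The pairwise coupling sum_j K(x_j - x_i) sin(theta_j - theta_i) is
// computed for all i at once as Im( exp(-i theta) .* IFFT( Khat .* FFT(exp(i theta)) ) ),
// which is exact for periodic boundaries.  Khat must be fft2 of the coupling
// kernel laid out on the full grid with its centre at element (0,0), already
// scaled by the global gain.  Each ghat is the fft2 of a (real) dendritic
// kernel in the same layout, already scaled to physical current units.
//
// positions are 0-based (row, col) indices.  Sampling happens at steps
// 0, sample_every, 2*sample_every, ... so sample s corresponds to time
// s * sample_every * dt.
// [[Rcpp::export]]
Rcpp::List cortex_run_cpp(const arma::mat& theta0,
                          const arma::mat& omega_hz,
                          const arma::cx_mat& khat,
                          const double dt,
                          const int n_steps,
                          const int sample_every,
                          const Rcpp::List& ghat_list,
                          const arma::imat& positions,
                          const bool record_phases) {
  const uword n1 = theta0.n_rows, n2 = theta0.n_cols;
  mat theta = theta0;
  const mat w = 2.0 * datum::pi * omega_hz;  // rad/s

  const int n_samples = (n_steps + sample_every - 1) / sample_every;
  const int n_kern = ghat_list.size();
  const int n_pos = positions.n_rows;

  std::vector<cx_mat> ghat(n_kern);
  for (int k = 0; k < n_kern; k++) ghat[k] = Rcpp::as<cx_mat>(ghat_list[k]);

  cx_vec esum(n_samples, fill::zeros);
  std::vector<mat> currents(n_kern);
  for (int k = 0; k < n_kern; k++) currents[k].set_size(n_pos, n_samples);
  cube phases;
  if (record_phases) phases.set_size(n1, n2, n_samples);

  cx_mat E(n1, n2), F(n1, n2), C(n1, n2);
  int s = 0;
  for (int step = 0; step < n_steps; step++) {
    E.set_real(cos(theta));
    E.set_imag(sin(theta));
    F = fft2(E);
    if (step % sample_every == 0) {
      esum(s) = F(0, 0);  // sum over the sheet of exp(i theta)
      for (int k = 0; k < n_kern; k++) {
        C = ifft2(ghat[k] % F);
        for (int p = 0; p < n_pos; p++)
          currents[k](p, s) = C(positions(p, 0), positions(p, 1)).real();
      }
      if (record_phases) phases.slice(s) = theta;
      s++;
    }
    C = ifft2(khat % F);
    theta += dt * (w + imag(conj(E) % C));
    // wrap to [0, 2*pi)
    theta -= 2.0 * datum::pi * floor(theta / (2.0 * datum::pi));
  }

  Rcpp::List cur(n_kern);
  for (int k = 0; k < n_kern; k++) cur[k] = currents[k];
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("theta") = theta,
      Rcpp::Named("esum") = esum,
      Rcpp::Named("currents") = cur);
  if (record_phases) out["phases"] = phases;
  return out;
}
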