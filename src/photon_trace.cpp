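#include <Rcpp.h>
using namespace Rcpp;

// Brownian-dynamics photon trace through a squared-Gaussian (two-photon)
// or Gaussian (one-photon) detection profile.
//
// Emitters take per-axis Gaussian steps of variance 2*D*dt inside a
// periodic box centred on the focus; the expected count of emitter i in a
// bin is brightness_i * dt * W(x,y,z) with
//   W = exp(-k*(x^2+y^2)/omega0^2 - k*z^2/z0^2),  k = 4 (2PE) or 2 (1PE),
// and the realised count is Poisson. Uses R's RNG, so set.seed() in R
// makes the trace deterministic.
//
// pos0: n x 3 initial positions (um); D, brightness: per-emitter;
// box: 3 box edge lengths (um).
// [[Rcpp::export]]
IntegerVector bd_photon_trace_cpp(NumericMatrix pos0, NumericVector D,
                                  NumericVector brightness, double omega0,
                                  double z0, NumericVector box, double dt,
                                  int n_bins, double profile_k) {
  const int n = pos0.nrow();
  std::vector<double> x(n), y(n), z(n), sd(n);
  for (int i = 0; i < n; ++i) {
    x[i] = pos0(i, 0);
    y[i] = pos0(i, 1);
    z[i] = pos0(i, 2);
    sd[i] = std::sqrt(2.0 * D[i] * dt);
  }
  const double Lx = box[0], Ly = box[1], Lz = box[2];
  const double iw2 = profile_k / (omega0 * omega0);
  const double iz2 = profile_k / (z0 * z0);
  IntegerVector counts(n_bins);

  for (int t = 0; t < n_bins; ++t) {
    double lambda = 0.0;
    for (int i = 0; i < n; ++i) {
      if (sd[i] > 0.0) {
        x[i] += R::rnorm(0.0, sd[i]);
        y[i] += R::rnorm(0.0, sd[i]);
        z[i] += R::rnorm(0.0, sd[i]);
        // periodic wrap into [-L/2, L/2)
        x[i] -= Lx * std::floor(x[i] / Lx + 0.5);
        y[i] -= Ly * std::floor(y[i] / Ly + 0.5);
        z[i] -= Lz * std::floor(z[i] / Lz + 0.5);
      }
      if (brightness[i] > 0.0)
        lambda += brightness[i] *
                  std::exp(-iw2 * (x[i] * x[i] + y[i] * y[i]) -
                           iz2 * z[i] * z[i]);
    }
    counts[t] = (int)R::rpois(lambda * dt);
  }
  return counts;
}
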