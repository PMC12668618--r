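// Euler-Maruyama simulation of the drift-diffusion model. Randomness comes
// from R's RNG (reproducible under set.seed()).

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List simulate_ddm_cpp(int n, double v, double a, double t0, double z,
                      double sigma, double dt, double max_t) {
  IntegerVector choice(n);     // 1 = upper, 0 = lower, NA = censored
  NumericVector rt(n);
  double sdt = sigma * std::sqrt(dt);
  double s2dt = sigma * sigma * dt;
  for (int i = 0; i < n; ++i) {
    double x = z * a, t = 0.0;
    int c = NA_INTEGER;
    while (t < max_t) {
      double x_new = x + v * dt + sdt * norm_rand();
      t += dt;
      if (x_new >= a) { c = 1; x = x_new; break; }
      if (x_new <= 0) { c = 0; x = x_new; break; }
      // Brownian-bridge correction: probability that the path crossed a
      // boundary inside the step even though both endpoints are interior
      double p_up = std::exp(-2.0 * (a - x) * (a - x_new) / s2dt);
      if (unif_rand() < p_up) { c = 1; x = x_new; break; }
      double p_dn = std::exp(-2.0 * x * x_new / s2dt);
      if (unif_rand() < p_dn) { c = 0; x = x_new; break; }
      x = x_new;
    }
    choice[i] = c;
    rt[i] = (c == NA_INTEGER) ? NA_REAL : t + t0;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}

// First-passage-time density at the LOWER boundary of a unit-variance DDM
// with boundary separation a, starting fraction z, drift v, evaluated at
// decision time t (already net of non-decision time). Small-time /
// large-time series per Navarro & Fuss (2009), truncation chosen for
// absolute error below `err`.
// [[Rcpp::export]]
NumericVector wfpt_lower_cpp(NumericVector t, double v, double a, double z,
                             double err) {
  int n = t.size();
  NumericVector out(n);
  for (int idx = 0; idx < n; ++idx) {
    double tt = t[idx];
    if (!(tt > 0)) { out[idx] = 0.0; continue; }
    double tnorm = tt / (a * a);            // normalized time
    // number of terms needed for each expansion
    double ks, kl;
    if (M_PI * tnorm * err < 1.0) {
      kl = std::sqrt(-2.0 * std::log(M_PI * tnorm * err) / (M_PI * M_PI * tnorm));
      kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tnorm)));
    } else kl = 1.0 / (M_PI * std::sqrt(tnorm));
    if (2.0 * std::sqrt(2.0 * M_PI * tnorm) * err < 1.0) {
      ks = 2.0 + std::sqrt(-2.0 * tnorm *
            std::log(2.0 * std::sqrt(2.0 * M_PI * tnorm) * err));
      ks = std::max(ks, std::sqrt(tnorm) + 1.0);
    } else ks = 2.0;
    double p;
    if (ks < kl) {                           // small-time expansion
      int K = (int)std::ceil(ks);
      p = 0.0;
      for (int k = -(K - 1) / 2; k <= K / 2; ++k) {
        double zz = z + 2.0 * k;
        p += zz * std::exp(-zz * zz / (2.0 * tnorm));
      }
      p /= std::sqrt(2.0 * M_PI * tnorm * tnorm * tnorm);
    } else {                                 // large-time expansion
      int K = (int)std::ceil(kl);
      p = 0.0;
      for (int k = 1; k <= K; ++k)
        p += k * std::exp(-k * k * M_PI * M_PI * tnorm / 2.0) *
             std::sin(k * M_PI * z);
      p *= M_PI;
    }
    // un-normalize: drift term and time scaling
    out[idx] = std::max(0.0, p * std::exp(-v * a * z - v * v * tt / 2.0) /
                             (a * a));
  }
  return out;
}
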