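#include <Rcpp.h>
#include "rng.h"

using namespace Rcpp;
using melsci::Rng;
using melsci::rnorm1;

// Standard normals from the package RNG; used for fixed-pattern generation
// and for statistical validation of the generator itself.
// [[Rcpp::export]]
NumericVector cpp_rnorm(double n, double seed, double stream) {
  R_xlen_t nn = (R_xlen_t)n;
  NumericVector out(nn);
  Rng r;
  r.seed((uint64_t)seed, (uint64_t)stream);
  for (R_xlen_t i = 0; i < nn; ++i) out[i] = rnorm1(r);
  return out;
}

// Dynamic speckle stack.
//
// Per pixel and per speckle average m = 1..n_avg, the optical field is
//   E(t) = sqrt(rho) * E_dyn(t) + sqrt(1 - rho) * E_stat
// where E_dyn is a stationary complex Gaussian AR(1) process sampled on a
// sub-frame grid of `substeps` midpoints per base exposure, with field
// autocorrelation exp(-dt / tau), and E_stat is drawn once per stack.
// Each frame records the time average of |E|^2 over its substeps (the
// camera's integration), averaged over the n_avg independent speckle
// realizations and scaled to the requested mean intensity.
//
// tau, rho, intensity are per-pixel vectors of length H*W (column-major).
// tau may be Inf (static). Returns an H x W x n_frames array.
// [[Rcpp::export]]
NumericVector cpp_sim_speckle(int H, int W, int n_frames, int substeps,
                              NumericVector tau, NumericVector rho,
                              NumericVector intensity, int n_avg,
                              double base_exposure, double seed,
                              double stream) {
  const int npix = H * W;
  NumericVector out(Dimension(H, W, n_frames));
  const double delta = base_exposure / substeps;
  const double isub = 1.0 / substeps;
  const double sd0 = std::sqrt(0.5);  // per-component stationary sd

  Rng r;
  r.seed((uint64_t)seed, (uint64_t)stream);

  std::vector<double> acc(n_frames);
  for (int p = 0; p < npix; ++p) {
    const double mu = intensity[p];
    if (mu == 0.0) continue;  // dark pixel: leave zeros (draws skipped)
    const double tp = tau[p];
    const double a = R_finite(tp) ? std::exp(-delta / tp) : 1.0;
    const double cinn = sd0 * std::sqrt(std::max(0.0, 1.0 - a * a));
    const double sr = std::sqrt(rho[p]);
    const double ss = std::sqrt(1.0 - rho[p]);
    std::fill(acc.begin(), acc.end(), 0.0);
    for (int m = 0; m < n_avg; ++m) {
      double esr = sd0 * rnorm1(r), esi = sd0 * rnorm1(r);  // static field
      double edr = sd0 * rnorm1(r), edi = sd0 * rnorm1(r);  // dynamic field
      for (int f = 0; f < n_frames; ++f) {
        double s = 0.0;
        for (int k = 0; k < substeps; ++k) {
          edr = a * edr + cinn * rnorm1(r);
          edi = a * edi + cinn * rnorm1(r);
          const double er = sr * edr + ss * esr;
          const double ei = sr * edi + ss * esi;
          s += er * er + ei * ei;
        }
        acc[f] += s * isub;
      }
    }
    const double scale = mu / n_avg;
    for (int f = 0; f < n_frames; ++f)
      out[p + (R_xlen_t)npix * f] = acc[f] * scale;
  }
  return out;
}

// Camera noise: per element, one Gaussian draw with variance
// n_dark + n_shot * I (dark and shot noise are independent Gaussians, so
// their sum is Gaussian with added variances), plus a per-pixel pattern
// that repeats identically in every frame. Returns a new array.
// [[Rcpp::export]]
NumericVector cpp_add_camera_noise(NumericVector frames, int npix,
                                   int n_frames, double n_shot, double n_dark,
                                   NumericVector pattern, double seed,
                                   double stream) {
  NumericVector out = clone(frames);
  Rng r;
  r.seed((uint64_t)seed, (uint64_t)stream);
  const bool has_pat = pattern.size() == npix;
  for (int f = 0; f < n_frames; ++f) {
    R_xlen_t off = (R_xlen_t)npix * f;
    for (int p = 0; p < npix; ++p) {
      const double I = out[off + p];
      const double v = n_dark + n_shot * (I > 0.0 ? I : 0.0);
      double x = I;
      if (v > 0.0) x += std::sqrt(v) * rnorm1(r);
      if (has_pat) x += pattern[p];
      out[off + p] = x;
    }
  }
  return out;
}
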