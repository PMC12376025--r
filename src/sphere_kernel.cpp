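#include <Rcpp.h>
#include <cmath>

// Polydisperse hard-sphere form-factor sum.
//
// For each q value returns
//   sum_j w_j * V_j * drho^2 * K(q r_j)^2
// with V_j = (4/3) pi r_j^3 and the sphere amplitude kernel
//   K(x) = 3 (sin x - x cos x) / x^3  (K -> 1 as x -> 0).
// Weights are assumed normalized by the caller (number-weighted
// quadrature of the radius distribution).
//
// Radius nodes from an equal-width bin quadrature are equally spaced, so
// sin/cos along the radius loop are advanced by the angle-addition
// recurrence (delta = q * bin width), costing two trig calls per q
// instead of two per (q, radius) pair.  Non-uniform node sets fall back
// to direct evaluation.
// [[Rcpp::export(name = ".sphere_pd_sum")]]
Rcpp::NumericVector sphere_pd_sum(Rcpp::NumericVector q,
                                  Rcpp::NumericVector radii,
                                  Rcpp::NumericVector weights,
                                  double drho) {
  const R_xlen_t nq = q.size(), nr = radii.size();
  Rcpp::NumericVector out(nq);
  const double c43pi = 4.0 / 3.0 * M_PI;
  std::vector<double> vw(nr);
  for (R_xlen_t j = 0; j < nr; ++j)
    vw[j] = weights[j] * c43pi * radii[j] * radii[j] * radii[j] * drho * drho;

  bool uniform = true;
  double h = (nr > 1) ? radii[1] - radii[0] : 0.0;
  for (R_xlen_t j = 2; j < nr; ++j)
    if (std::fabs((radii[j] - radii[j - 1]) - h) > 1e-9 * std::fabs(h)) {
      uniform = false;
      break;
    }

  for (R_xlen_t i = 0; i < nq; ++i) {
    const double qi = q[i];
    double acc = 0.0;
    if (uniform && nr > 1) {
      const double delta = qi * h;
      const double sd = std::sin(delta), cd = std::cos(delta);
      double x = qi * radii[0];
      double s = std::sin(x), c = std::cos(x);
      for (R_xlen_t j = 0; j < nr; ++j) {
        double k;
        if (x < 1e-2) {
          const double x2 = x * x;
          k = 1.0 - x2 / 10.0 + x2 * x2 / 280.0;  // series for small qr
        } else {
          k = 3.0 * (s - x * c) / (x * x * x);
        }
        acc += vw[j] * k * k;
        const double s2 = s * cd + c * sd;
        c = c * cd - s * sd;
        s = s2;
        x += delta;
      }
    } else {
      for (R_xlen_t j = 0; j < nr; ++j) {
        const double x = qi * radii[j];
        double k;
        if (x < 1e-2) {
          const double x2 = x * x;
          k = 1.0 - x2 / 10.0 + x2 * x2 / 280.0;
        } else {
          k = 3.0 * (std::sin(x) - x * std::cos(x)) / (x * x * x);
        }
        acc += vw[j] * k * k;
      }
    }
    out[i] = acc;
  }
  return out;
}
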