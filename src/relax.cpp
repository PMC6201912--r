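#include <Rcpp.h>
using namespace Rcpp;

// Net force field on every cone: inverse-square repulsion from all other
// cones plus inverse-square attraction toward the field center (0, 0).
// The attraction is softened near the origin (d^2 -> d^2 + soft2) so the
// central force stays finite.  Coincident pairs (d^2 below tol) contribute
// no repulsion; their count is returned so the caller can jitter and retry.
// [[Rcpp::export(name = ".mosaic_forces")]]
List mosaic_forces(NumericVector x, NumericVector y,
                   double repulsion, double attraction,
                   double soft2 = 0.0, double tol2 = 1e-12) {
  const int n = x.size();
  NumericVector fx(n), fy(n);
  int n_coincident = 0;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      const double dx = x[i] - x[j];
      const double dy = y[i] - y[j];
      const double d2 = dx * dx + dy * dy;
      if (d2 < tol2) { ++n_coincident; continue; }
      const double w = repulsion / (d2 * std::sqrt(d2));
      fx[i] += dx * w; fy[i] += dy * w;
      fx[j] -= dx * w; fy[j] -= dy * w;
    }
    const double dc2 = x[i] * x[i] + y[i] * y[i] + soft2;
    if (dc2 >= tol2) {
      const double w = attraction / (dc2 * std::sqrt(dc2));
      fx[i] -= x[i] * w;
      fy[i] -= y[i] * w;
    }
  }
  return List::create(_["fx"] = fx, _["fy"] = fy,
                      _["n_coincident"] = n_coincident);
}
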