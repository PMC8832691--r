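// 2D global gamma index. The optimized engine enumerates candidate
// displacements sorted by distance and stops as soon as the distance term
// alone exceeds the current minimum, which is exact relative to the
// interpolation grid; the exhaustive engine evaluates every displacement.
#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

struct Disp { double dx, dy, d2; };

static inline double interp_eval(const NumericMatrix& E, double fx, double fy,
                                 bool& ok) {
  int nx = E.nrow(), ny = E.ncol();
  if (fx < 0.0 || fy < 0.0 || fx > nx - 1.0 || fy > ny - 1.0) { ok = false; return 0.0; }
  ok = true;
  int i0 = std::min((int)std::floor(fx), nx - 2);
  int j0 = std::min((int)std::floor(fy), ny - 2);
  double ax = fx - i0, ay = fy - j0;
  return (1 - ax) * (1 - ay) * E(i0, j0) + ax * (1 - ay) * E(i0 + 1, j0) +
         (1 - ax) * ay * E(i0, j0 + 1) + ax * ay * E(i0 + 1, j0 + 1);
}

// [[Rcpp::export]]
NumericMatrix cpp_gamma(const NumericMatrix& ref, const NumericMatrix& eval,
                        double pitch_x, double pitch_y, double dd_abs,
                        double dta_mm, double thresh_abs, double radius_mm,
                        double step_mm, bool early_exit) {
  const int nx = ref.nrow(), ny = ref.ncol();
  std::vector<Disp> disp;
  int nstep = (int)std::floor(radius_mm / step_mm + 1e-9);
  for (int a = -nstep; a <= nstep; ++a)
    for (int b = -nstep; b <= nstep; ++b) {
      double dx = a * step_mm, dy = b * step_mm, d2 = dx * dx + dy * dy;
      if (d2 <= radius_mm * radius_mm + 1e-9)
        disp.push_back({dx, dy, d2});
    }
  std::sort(disp.begin(), disp.end(),
            [](const Disp& u, const Disp& v) { return u.d2 < v.d2; });
  const double dta2 = dta_mm * dta_mm, dd2 = dd_abs * dd_abs;
  NumericMatrix out(nx, ny);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double r = ref(i, j);
      if (r < thresh_abs) { out(i, j) = NA_REAL; continue; }
      double best = R_PosInf;
      for (const Disp& d : disp) {
        double dist_term = d.d2 / dta2;
        if (early_exit && dist_term >= best) break;
        if (dist_term >= best) continue;
        bool ok;
        double e = interp_eval(eval, i + d.dx / pitch_x, j + d.dy / pitch_y, ok);
        if (!ok) continue;
        double diff = e - r;
        double g2 = dist_term + diff * diff / dd2;
        if (g2 < best) best = g2;
      }
      out(i, j) = std::sqrt(best);
    }
  return out;
}
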