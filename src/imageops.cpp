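// Planar image primitives shared across modules: bilinear sampling on
// uniform grids, separable Gaussian blur (zero padded), block-mean
// downsampling. Matrices are indexed [x, y] = [crossline, inline].
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double sample_bilinear(const NumericMatrix& V,
                                     double fx, double fy, double fill) {
  int nx = V.nrow(), ny = V.ncol();
  const double eps = 1e-6;  // tolerate rounding at the exact grid border
  if (fx < -eps || fy < -eps || fx > nx - 1.0 + eps || fy > ny - 1.0 + eps)
    return fill;
  if (fx < 0.0) fx = 0.0;
  if (fy < 0.0) fy = 0.0;
  if (fx > nx - 1.0) fx = nx - 1.0;
  if (fy > ny - 1.0) fy = ny - 1.0;
  int i0 = (int)std::floor(fx), j0 = (int)std::floor(fy);
  if (i0 >= nx - 1) i0 = nx - 2;
  if (j0 >= ny - 1) j0 = ny - 2;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  double ax = fx - i0, ay = fy - j0;
  return (1 - ax) * (1 - ay) * V(i0, j0) + ax * (1 - ay) * V(i0 + 1, j0) +
         (1 - ax) * ay * V(i0, j0 + 1) + ax * ay * V(i0 + 1, j0 + 1);
}

// [[Rcpp::export]]
NumericMatrix cpp_bilinear_grid(const NumericMatrix& V,
                                double sx0, double sdx, double sy0, double sdy,
                                const NumericVector& tx, const NumericVector& ty,
                                double fill) {
  NumericMatrix out(tx.size(), ty.size());
  for (int j = 0; j < ty.size(); ++j) {
    double fy = (ty[j] - sy0) / sdy;
    for (int i = 0; i < tx.size(); ++i) {
      double fx = (tx[i] - sx0) / sdx;
      out(i, j) = sample_bilinear(V, fx, fy, fill);
    }
  }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_bilinear_map(const NumericMatrix& V,
                               double sx0, double sdx, double sy0, double sdy,
                               const NumericMatrix& X, const NumericMatrix& Y,
                               double fill) {
  NumericMatrix out(X.nrow(), X.ncol());
  for (int j = 0; j < X.ncol(); ++j)
    for (int i = 0; i < X.nrow(); ++i)
      out(i, j) = sample_bilinear(V, (X(i, j) - sx0) / sdx,
                                  (Y(i, j) - sy0) / sdy, fill);
  return out;
}

static std::vector<double> gauss_kernel(double sigma) {
  int r = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& v : k) v /= s;
  return k;
}

// [[Rcpp::export]]
NumericMatrix cpp_gauss_blur(const NumericMatrix& V,
                             double sigma_x_px, double sigma_y_px) {
  int nx = V.nrow(), ny = V.ncol();
  NumericMatrix tmp(nx, ny), out(nx, ny);
  if (sigma_x_px > 1e-9) {
    std::vector<double> k = gauss_kernel(sigma_x_px);
    int r = ((int)k.size() - 1) / 2;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        int lo = std::max(-r, -i), hi = std::min(r, nx - 1 - i);
        for (int d = lo; d <= hi; ++d) s += k[d + r] * V(i + d, j);
        tmp(i, j) = s;
      }
  } else tmp = clone(V);
  if (sigma_y_px > 1e-9) {
    std::vector<double> k = gauss_kernel(sigma_y_px);
    int r = ((int)k.size() - 1) / 2;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        double s = 0.0;
        int lo = std::max(-r, -j), hi = std::min(r, ny - 1 - j);
        for (int d = lo; d <= hi; ++d) s += k[d + r] * tmp(i, j + d);
        out(i, j) = s;
      }
  } else out = tmp;
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_block_mean(const NumericMatrix& V, int fx, int fy) {
  int nx = V.nrow() / fx, ny = V.ncol() / fy;
  NumericMatrix out(nx, ny);
  double w = 1.0 / (fx * fy);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      double s = 0.0;
      for (int dj = 0; dj < fy; ++dj)
        for (int di = 0; di < fx; ++di)
          s += V(i * fx + di, j * fy + dj);
      out(i, j) = s * w;
    }
  return out;
}
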