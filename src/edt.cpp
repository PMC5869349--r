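#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// 1D lower-envelope pass generalised to a physical sample spacing w (mm).
// f holds squared distances on input and output.
static void dt1d(std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z,
                 int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  const double w2 = w * w;
  // infinite entries carry no parabola; build the envelope from finite ones
  int q0 = -1;
  for (int q = 0; q < n; q++)
    if (f[q] < INF) { q0 = q; break; }
  if (q0 < 0) {
    for (int q = 0; q < n; q++) d[q] = INF;
    return;
  }
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; q++) {
    if (f[q] == INF) continue;
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * (double)q * q) - (f[p] + w2 * (double)p * p)) /
          (2.0 * w2 * (q - p));
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    int p = v[k];
    d[q] = w2 * (double)(q - p) * (q - p) + f[p];
  }
}

//' @noRd
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const double INF = std::numeric_limits<double>::infinity();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++)
    out[i] = (mask[i] == TRUE) ? 0.0 : INF;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x (fastest-varying index)
  for (int kz = 0; kz < nz; kz++)
    for (int ky = 0; ky < ny; ky++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + (R_xlen_t)ky * nx;
      for (int i = 0; i < nx; i++) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; i++) out[base + i] = d[i];
    }
  // pass along y
  for (int kz = 0; kz < nz; kz++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)kz * nx * ny + kx;
      for (int i = 0; i < ny; i++) f[i] = out[base + (R_xlen_t)i * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int i = 0; i < ny; i++) out[base + (R_xlen_t)i * nx] = d[i];
    }
  // pass along z
  for (int ky = 0; ky < ny; ky++)
    for (int kx = 0; kx < nx; kx++) {
      R_xlen_t base = (R_xlen_t)ky * nx + kx;
      for (int i = 0; i < nz; i++) f[i] = out[base + (R_xlen_t)i * nx * ny];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int i = 0; i < nz; i++) out[base + (R_xlen_t)i * nx * ny] = d[i];
    }
  return out;
}

// Separable 1D convolution along one axis (0 = x, 1 = y, 2 = z) with
// replicated (nearest) boundary handling; kernel must have odd length.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector img, IntegerVector dim,
                                NumericVector kernel, int axis) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t n = (R_xlen_t)nx * ny * nz;
  int klen = kernel.size();
  int half = klen / 2;
  NumericVector out(n);

  int len = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? (R_xlen_t)nx
                                                  : (R_xlen_t)nx * ny;
  int no = (axis == 0) ? ny : nx;
  int ni = (axis == 0) ? nz : (axis == 1) ? nz : ny;
  R_xlen_t so = (axis == 0) ? (R_xlen_t)nx : 1;
  R_xlen_t si = (axis == 0) ? (R_xlen_t)nx * ny
              : (axis == 1) ? (R_xlen_t)nx * ny
                            : (R_xlen_t)nx;

  std::vector<double> line(len);
  for (int a = 0; a < ni; a++)
    for (int b = 0; b < no; b++) {
      R_xlen_t base = a * si + b * so;
      for (int i = 0; i < len; i++) line[i] = img[base + i * stride];
      for (int i = 0; i < len; i++) {
        double acc = 0.0;
        for (int k = 0; k < klen; k++) {
          int j = i + k - half;
          if (j < 0) j = 0;
          if (j >= len) j = len - 1;
          acc += kernel[k] * line[j];
        }
        out[base + i * stride] = acc;
      }
    }
  return out;
}
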