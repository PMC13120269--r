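#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// Separable squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// Theory of Computing 2012), generalized to anisotropic sampling: samples sit
// at physical positions i * step. Infinite entries (no source on this line
// yet) are skipped when building the lower envelope; the caller guarantees at
// least one finite entry.
static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 std::vector<int> &v, std::vector<double> &z, int n,
                 double step) {
  const double INF = std::numeric_limits<double>::infinity();
  const double s2 = step * step;
  int q0 = 0;
  while (f[q0] == INF) ++q0;
  int k = 0;
  v[0] = q0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = q0 + 1; q < n; ++q) {
    if (f[q] == INF) continue;
    double s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
               (2.0 * s2 * (q - v[k]));
    while (s <= z[k]) {
      --k;
      s = ((f[q] + s2 * q * q) - (f[v[k]] + s2 * v[k] * v[k])) /
          (2.0 * s2 * (q - v[k]));
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dx = step * (q - v[k]);
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = std::numeric_limits<double>::infinity();
  const R_xlen_t n = static_cast<R_xlen_t>(nx) * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : INF;

  const int mdim = std::max(nx, std::max(ny, nz));
  std::vector<double> f(mdim), d(mdim), z(mdim + 1);
  std::vector<int> v(mdim);

  // pass along x (fastest-varying)
  for (int kz = 0; kz < nz; ++kz)
    for (int ky = 0; ky < ny; ++ky) {
      const R_xlen_t base = static_cast<R_xlen_t>(kz) * nx * ny +
                            static_cast<R_xlen_t>(ky) * nx;
      bool any_finite = false;
      for (int i = 0; i < nx; ++i) {
        f[i] = out[base + i];
        if (f[i] < INF) any_finite = true;
      }
      if (!any_finite) continue;
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }

  // pass along y
  for (int kz = 0; kz < nz; ++kz)
    for (int kx = 0; kx < nx; ++kx) {
      const R_xlen_t base = static_cast<R_xlen_t>(kz) * nx * ny + kx;
      bool any_finite = false;
      for (int j = 0; j < ny; ++j) {
        f[j] = out[base + static_cast<R_xlen_t>(j) * nx];
        if (f[j] < INF) any_finite = true;
      }
      if (!any_finite) continue;
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j)
        out[base + static_cast<R_xlen_t>(j) * nx] = d[j];
    }

  // pass along z
  for (int ky = 0; ky < ny; ++ky)
    for (int kx = 0; kx < nx; ++kx) {
      const R_xlen_t base = static_cast<R_xlen_t>(ky) * nx + kx;
      bool any_finite = false;
      for (int k = 0; k < nz; ++k) {
        f[k] = out[base + static_cast<R_xlen_t>(k) * nx * ny];
        if (f[k] < INF) any_finite = true;
      }
      if (!any_finite) continue;
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k)
        out[base + static_cast<R_xlen_t>(k) * nx * ny] = d[k];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}
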