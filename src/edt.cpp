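#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// large finite sentinel: avoids Inf-Inf in the parabola intersections;
// any real in-grid squared distance is far below this
static const double DT_BIG = 1e20;

// 1D squared distance transform of a sampled function (Felzenszwalb &
// Huttenlocher), sample spacing h along the axis.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double h) {
  int k = 0;
  v[0] = 0;
  z[0] = -DT_BIG;
  z[1] = DT_BIG;
  for (int q = 1; q < n; ++q) {
    double qq = (double)q * h;
    double s;
    while (true) {
      double pp = (double)v[k] * h;
      s = ((f[q] + qq * qq) - (f[v[k]] + pp * pp)) / (2 * qq - 2 * pp);
      if (s <= z[k] && k > 0) { --k; } else break;
    }
    if (s <= z[k] && k == 0) {
      v[0] = q;
    } else {
      ++k;
      v[k] = q;
    }
    z[k] = (k == 0) ? -DT_BIG : s;
    z[k + 1] = DT_BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double qq = (double)q * h;
    while (z[k + 1] < qq) ++k;
    double pp = (double)v[k] * h;
    d[q] = (qq - pp) * (qq - pp) + f[v[k]];
  }
}

// Exact Euclidean distance (mm) from every voxel center to the nearest TRUE
// voxel center of `mask`, on an anisotropic grid.
// [[Rcpp::export(name = ".edt_cpp")]]
NumericVector edt_cpp(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = mask[i] ? 0.0 : DT_BIG;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  for (int k = 0; k < nz; ++k)            // pass along x
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  for (int k = 0; k < nz; ++k)            // pass along y
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f, d, v, z, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)            // pass along z
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * sz];
      dt1d(f, d, v, z, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * sz] = d[k];
    }
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = (out[i] >= DT_BIG) ? R_PosInf : std::sqrt(out[i]);
  return out;
}
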