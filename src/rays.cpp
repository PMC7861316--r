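#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// nearest-voxel lookup index into a column-major 3D array; -1 if outside
static inline R_xlen_t voxel_at(double px, double py, double pz,
                                const double* origin, const double* spacing,
                                const int* dims) {
  int i = (int)std::lround((px - origin[0]) / spacing[0]);
  int j = (int)std::lround((py - origin[1]) / spacing[1]);
  int k = (int)std::lround((pz - origin[2]) / spacing[2]);
  if (i < 0 || j < 0 || k < 0 || i >= dims[0] || j >= dims[1] || k >= dims[2])
    return -1;
  return (R_xlen_t)k * dims[0] * dims[1] + (R_xlen_t)j * dims[0] + i;
}

// Trace divergent rays from `source` through each target point (mm), marching
// with step `step` (mm) until the ray leaves the body (or the grid bounding
// box).  density: per-voxel linear-attenuation density (0 outside body).
// Accumulates:
//   benefit  = sum over targets of exp(-mu * WED at the target point)
//   penalty[o] = sum over targets of attenuation-weighted in-ray path length
//                through OAR o (mm, weighted by exp(-mu * WED at sample))
// [[Rcpp::export(name = ".ray_trace_cpp")]]
List ray_trace_cpp(NumericVector density, LogicalVector body, List oars,
                   NumericMatrix targets, NumericVector source,
                   NumericVector origin, NumericVector spacing,
                   IntegerVector dims, double mu, double step) {
  const int n_oar = oars.size();
  std::vector<const int*> om(n_oar);
  for (int o = 0; o < n_oar; ++o)
    om[o] = LOGICAL(((LogicalVector)oars[o]));
  const double* dens = REAL(density);
  const int* bod = LOGICAL(body);
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  double orig[3] = {origin[0], origin[1], origin[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  int dm[3] = {dims[0], dims[1], dims[2]};
  // grid bounding box (voxel extents, half a voxel beyond the centers)
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = orig[a] - 0.5 * sp[a];
    hi[a] = orig[a] + (dm[a] - 0.5) * sp[a];
  }
  (void)ox; (void)oy; (void)oz;
  double benefit = 0.0;
  NumericVector penalty(n_oar);
  const int nt = targets.nrow();
  for (int t = 0; t < nt; ++t) {
    double dx = targets(t, 0) - source[0];
    double dy = targets(t, 1) - source[1];
    double dz = targets(t, 2) - source[2];
    double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (dist <= 0) continue;
    dx /= dist; dy /= dist; dz /= dist;
    // clip [0, inf) ray against the grid bbox to skip empty space
    double t0 = 0.0, t1 = 1e12;
    double sdir[3] = {dx, dy, dz}, spt[3] = {source[0], source[1], source[2]};
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(sdir[a]) < 1e-12) {
        if (spt[a] < lo[a] || spt[a] > hi[a]) { miss = true; break; }
      } else {
        double ta = (lo[a] - spt[a]) / sdir[a];
        double tb = (hi[a] - spt[a]) / sdir[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
        if (t0 > t1) { miss = true; break; }
      }
    }
    if (miss) continue;
    double wed = 0.0;       // water-equivalent depth from body entry (mm)
    bool entered = false;
    bool reached = false;   // passed the target point
    double wed_target = 0.0;
    for (double s = t0 + 0.5 * step; s <= t1; s += step) {
      if (!reached && s >= dist) {
        wed_target = wed;
        reached = true;
      }
      double px = source[0] + s * dx;
      double py = source[1] + s * dy;
      double pz = source[2] + s * dz;
      R_xlen_t v = voxel_at(px, py, pz, orig, sp, dm);
      if (v < 0) continue;
      bool inb = bod[v] != 0;
      if (inb) entered = true;
      else if (entered) break;   // left the body: stop this ray
      if (!inb) continue;
      double att = std::exp(-mu * wed);
      for (int o = 0; o < n_oar; ++o)
        if (om[o][v]) penalty[o] += step * att;
      wed += dens[v] * step;
    }
    if (!reached) wed_target = wed;
    benefit += std::exp(-mu * wed_target);
  }
  return List::create(_["benefit"] = benefit, _["penalty"] = penalty);
}

// Water-equivalent depth (mm) from body entry to each query point, marching
// from `source` toward each point.  Used by the dose synthesizer.
// [[Rcpp::export(name = ".wed_cpp")]]
NumericVector wed_cpp(NumericVector density, LogicalVector body,
                      NumericMatrix points, NumericVector source,
                      NumericVector origin, NumericVector spacing,
                      IntegerVector dims, double step) {
  const double* dens = REAL(density);
  const int* bod = LOGICAL(body);
  double orig[3] = {origin[0], origin[1], origin[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  int dm[3] = {dims[0], dims[1], dims[2]};
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = orig[a] - 0.5 * sp[a];
    hi[a] = orig[a] + (dm[a] - 0.5) * sp[a];
  }
  const int np = points.nrow();
  NumericVector out(np);
  for (int t = 0; t < np; ++t) {
    double dx = points(t, 0) - source[0];
    double dy = points(t, 1) - source[1];
    double dz = points(t, 2) - source[2];
    double dist = std::sqrt(dx * dx + dy * dy + dz * dz);
    if (dist <= 0) { out[t] = 0.0; continue; }
    dx /= dist; dy /= dist; dz /= dist;
    double t0 = 0.0, t1 = dist;
    double sdir[3] = {dx, dy, dz}, spt[3] = {source[0], source[1], source[2]};
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(sdir[a]) < 1e-12) {
        if (spt[a] < lo[a] || spt[a] > hi[a]) { miss = true; break; }
      } else {
        double ta = (lo[a] - spt[a]) / sdir[a];
        double tb = (hi[a] - spt[a]) / sdir[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    if (miss || t0 > t1) { out[t] = 0.0; continue; }
    double wed = 0.0;
    for (double s = t0 + 0.5 * step; s <= t1; s += step) {
      double px = source[0] + s * dx;
      double py = source[1] + s * dy;
      double pz = source[2] + s * dz;
      R_xlen_t v = voxel_at(px, py, pz, orig, sp, dm);
      if (v < 0) continue;
      if (bod[v]) wed += dens[v] * step;
    }
    out[t] = wed;
  }
  return out;
}
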