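#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Voxel grid convention: value at voxel centre, centre of voxel (i,j,k)
// (0-based) at origin + (i,j,k)*spacing; grid extent is the half-open box
// [origin - spacing/2, origin + (dims-1/2)*spacing).

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// Exact Siddon-style voxel traversal from `source` to each row of `targets`.
// Returns an n x 2 matrix:
//   [,1] radiological path length in g/cm^2 (density assumed g/cm^3, lengths mm)
//   [,2] physical path length (mm) from the first voxel with density >= air_thresh
//        to the target; -1 if the ray meets no such voxel before the target.
// [[Rcpp::export]]
NumericMatrix cpp_rad_depth(NumericVector vals, IntegerVector dims,
                            NumericVector origin, NumericVector spacing,
                            NumericVector source, NumericMatrix targets,
                            double air_thresh) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = targets.nrow();
  NumericMatrix out(n, 2);
  double lo[3], hi[3];
  for (int a = 0; a < 3; ++a) {
    lo[a] = origin[a] - 0.5 * spacing[a];
    hi[a] = lo[a] + dims[a] * spacing[a];
  }
  const double *v = REAL(vals);
  for (int r = 0; r < n; ++r) {
    double s[3] = { source[0], source[1], source[2] };
    double e[3] = { targets(r, 0), targets(r, 1), targets(r, 2) };
    double d[3] = { e[0] - s[0], e[1] - s[1], e[2] - s[2] };
    double L = std::sqrt(d[0] * d[0] + d[1] * d[1] + d[2] * d[2]);
    double t0 = 0.0, t1 = 1.0; // param range: 0 at source, 1 at target
    bool miss = false;
    for (int a = 0; a < 3 && !miss; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (s[a] < lo[a] || s[a] >= hi[a]) miss = true;
      } else {
        double ta = (lo[a] - s[a]) / d[a];
        double tb = (hi[a] - s[a]) / d[a];
        if (ta > tb) std::swap(ta, tb);
        if (ta > t0) t0 = ta;
        if (tb < t1) t1 = tb;
      }
    }
    if (miss || t1 <= t0 || L <= 0.0) { out(r, 0) = 0.0; out(r, 1) = -1.0; continue; }
    // walk voxel boundaries between t0 and t1
    double rad = 0.0, tfirst = -1.0;
    double t = t0;
    // index of current voxel at entry (nudge inside)
    while (t < t1 - 1e-12) {
      double tm = t; // find exit of current voxel
      double pmid[3];
      double tprobe = t + 1e-9 * (t1 - t0 > 1e-9 ? (t1 - t0) : 1.0);
      for (int a = 0; a < 3; ++a) pmid[a] = s[a] + tprobe * d[a];
      int ix = (int)std::floor((pmid[0] - lo[0]) / spacing[0]);
      int iy = (int)std::floor((pmid[1] - lo[1]) / spacing[1]);
      int iz = (int)std::floor((pmid[2] - lo[2]) / spacing[2]);
      ix = ix < 0 ? 0 : (ix >= nx ? nx - 1 : ix);
      iy = iy < 0 ? 0 : (iy >= ny ? ny - 1 : iy);
      iz = iz < 0 ? 0 : (iz >= nz ? nz - 1 : iz);
      int idx3[3] = { ix, iy, iz };
      double tnext = t1;
      for (int a = 0; a < 3; ++a) {
        if (std::fabs(d[a]) < 1e-12) continue;
        double bound = d[a] > 0 ? lo[a] + (idx3[a] + 1) * spacing[a]
                                : lo[a] + idx3[a] * spacing[a];
        double tc = (bound - s[a]) / d[a];
        if (tc > t + 1e-12 && tc < tnext) tnext = tc;
      }
      if (tnext <= t) { tnext = t1; }
      double seg = (tnext - t) * L; // mm
      double rho = v[ix + (R_xlen_t)nx * (iy + (R_xlen_t)ny * iz)];
      rad += rho * seg;
      if (tfirst < 0.0 && rho >= air_thresh) tfirst = t;
      t = tnext;
      tm = tm; // silence unused warning
    }
    out(r, 0) = rad / 10.0;                       // mm * g/cm^3 -> g/cm^2
    out(r, 1) = tfirst < 0.0 ? -1.0 : (1.0 - tfirst) * L; // mm
  }
  return out;
}

// Trilinear interpolation of a voxel volume at arbitrary points (mm).
// Points outside the convex hull of voxel centres return NA.
// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vals, IntegerVector dims,
                            NumericVector origin, NumericVector spacing,
                            NumericMatrix pts) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = pts.nrow();
  NumericVector out(n);
  const double *v = REAL(vals);
  for (int r = 0; r < n; ++r) {
    double f[3];
    bool ok = true;
    for (int a = 0; a < 3; ++a) {
      f[a] = (pts(r, a) - origin[a]) / spacing[a];
      if (f[a] < -1e-9 || f[a] > dims[a] - 1 + 1e-9) ok = false;
    }
    if (!ok) { out[r] = NA_REAL; continue; }
    int i0 = (int)std::floor(clampd(f[0], 0, nx - 1));
    int j0 = (int)std::floor(clampd(f[1], 0, ny - 1));
    int k0 = (int)std::floor(clampd(f[2], 0, nz - 1));
    if (i0 > nx - 2) i0 = nx > 1 ? nx - 2 : 0;
    if (j0 > ny - 2) j0 = ny > 1 ? ny - 2 : 0;
    if (k0 > nz - 2) k0 = nz > 1 ? nz - 2 : 0;
    double fx = clampd(f[0] - i0, 0.0, 1.0);
    double fy = clampd(f[1] - j0, 0.0, 1.0);
    double fz = clampd(f[2] - k0, 0.0, 1.0);
    int i1 = nx > 1 ? i0 + 1 : i0, j1 = ny > 1 ? j0 + 1 : j0, k1 = nz > 1 ? k0 + 1 : k0;
    if (nx == 1) fx = 0.0;
    if (ny == 1) fy = 0.0;
    if (nz == 1) fz = 0.0;
#define V(i, j, k) v[(i) + (R_xlen_t)nx * ((j) + (R_xlen_t)ny * (k))]
    double c00 = V(i0, j0, k0) * (1 - fx) + V(i1, j0, k0) * fx;
    double c10 = V(i0, j1, k0) * (1 - fx) + V(i1, j1, k0) * fx;
    double c01 = V(i0, j0, k1) * (1 - fx) + V(i1, j0, k1) * fx;
    double c11 = V(i0, j1, k1) * (1 - fx) + V(i1, j1, k1) * fx;
#undef V
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out[r] = c0 * (1 - fz) + c1 * fz;
  }
  return out;
}

// Even-odd rule point-in-polygon for a batch of points. Vertices need not be
// closed (first vertex repeated); edges wrap around.
// [[Rcpp::export]]
LogicalVector cpp_point_in_poly(NumericVector px, NumericVector py,
                                NumericVector vx, NumericVector vy) {
  const int n = px.size(), m = vx.size();
  LogicalVector out(n);
  for (int r = 0; r < n; ++r) {
    bool inside = false;
    double x = px[r], y = py[r];
    for (int i = 0, j = m - 1; i < m; j = i++) {
      if (((vy[i] > y) != (vy[j] > y)) &&
          (x < (vx[j] - vx[i]) * (y - vy[i]) / (vy[j] - vy[i]) + vx[i]))
        inside = !inside;
    }
    out[r] = inside;
  }
  return out;
}
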