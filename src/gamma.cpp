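// Global 3-D gamma engine: reference points vs. an evaluated dose lattice.
//
// For each reference point the evaluated grid is sampled by trilinear
// interpolation on a shared fine offset lattice (step <= DTA/10 for every
// criterion), offsets visited in order of increasing distance with exact
// pruning: a criterion stops contributing once the spatial term alone
// exceeds its current best (or the gamma cap). All criteria share one
// candidate lattice, which makes gamma passing rates exactly monotone in
// criterion leniency on any dose pair.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

struct Offset { float d; short ix, iy, iz; };

static inline bool trilinear(const double* v, const int* dims,
                             const double* org, const double* sp,
                             double x, double y, double z, double* out) {
  double fx = (x - org[0]) / sp[0];
  double fy = (y - org[1]) / sp[1];
  double fz = (z - org[2]) / sp[2];
  if (fx < 0 || fy < 0 || fz < 0 ||
      fx > dims[0] - 1 || fy > dims[1] - 1 || fz > dims[2] - 1)
    return false;
  int ix = (int)fx, iy = (int)fy, iz = (int)fz;
  if (ix == dims[0] - 1) --ix;
  if (iy == dims[1] - 1) --iy;
  if (iz == dims[2] - 1) --iz;
  if (dims[0] == 1) ix = 0;
  if (dims[1] == 1) iy = 0;
  if (dims[2] == 1) iz = 0;
  double tx = fx - ix, ty = fy - iy, tz = fz - iz;
  size_t nx = dims[0], nxy = (size_t)dims[0] * dims[1];
  const double* p = v + ix + iy * nx + iz * nxy;
  size_t sx = (dims[0] > 1) ? 1 : 0;
  size_t sy = (dims[1] > 1) ? nx : 0;
  size_t sz = (dims[2] > 1) ? nxy : 0;
  double c00 = p[0] * (1 - tx) + p[sx] * tx;
  double c10 = p[sy] * (1 - tx) + p[sy + sx] * tx;
  double c01 = p[sz] * (1 - tx) + p[sz + sx] * tx;
  double c11 = p[sz + sy] * (1 - tx) + p[sz + sy + sx] * tx;
  *out = (c00 * (1 - ty) + c10 * ty) * (1 - tz) +
         (c01 * (1 - ty) + c11 * ty) * tz;
  return true;
}

// [[Rcpp::export]]
NumericVector trilinear_cpp(NumericMatrix points, NumericVector origin,
                            NumericVector spacing, IntegerVector dims,
                            NumericVector values) {
  int n = points.nrow();
  NumericVector out(n);
  int d[3] = {dims[0], dims[1], dims[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  for (int i = 0; i < n; ++i) {
    double val;
    if (!trilinear(REAL(values), d, org, sp,
                   points(i, 0), points(i, 1), points(i, 2), &val))
      stop("point %d is outside the dose grid", i + 1);
    out[i] = val;
  }
  return out;
}

// dd_abs: absolute dose tolerance per criterion (Gy); dta: mm;
// stop_radius: mm search bound per criterion (min(search_factor, cap)*DTA);
// step: offset lattice step in mm; cap: gamma values are reported capped.
// Returns [n_points x n_criteria].
// [[Rcpp::export]]
NumericMatrix gamma_points_cpp(NumericMatrix ref_pos, NumericVector ref_dose,
                               NumericVector origin, NumericVector spacing,
                               IntegerVector dims, NumericVector values,
                               NumericVector dd_abs, NumericVector dta,
                               NumericVector stop_radius,
                               double step, double cap, int refine) {
  int n = ref_pos.nrow(), K = dd_abs.size();
  double rmax = 0;
  for (int k = 0; k < K; ++k) rmax = std::max(rmax, stop_radius[k]);
  int m = (int)std::ceil(rmax / step);
  std::vector<Offset> offs;
  offs.reserve((size_t)(4.2 * m * m * m + 8 * m + 8));
  for (int iz = -m; iz <= m; ++iz)
    for (int iy = -m; iy <= m; ++iy)
      for (int ix = -m; ix <= m; ++ix) {
        double d = step * std::sqrt((double)ix * ix + (double)iy * iy +
                                    (double)iz * iz);
        if (d <= rmax)
          offs.push_back({(float)d, (short)ix, (short)iy, (short)iz});
      }
  std::sort(offs.begin(), offs.end(),
            [](const Offset& a, const Offset& b) { return a.d < b.d; });

  NumericMatrix out(n, K);
  int dgrid[3] = {dims[0], dims[1], dims[2]};
  double org[3] = {origin[0], origin[1], origin[2]};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  const double* v = REAL(values);
  std::vector<double> best(K), stopr(K);
  std::vector<double> bx(K), by(K), bz(K);  // argmin offsets (mm)
  for (int i = 0; i < n; ++i) {
    double x = ref_pos(i, 0), y = ref_pos(i, 1), z = ref_pos(i, 2);
    double dr = ref_dose[i];
    for (int k = 0; k < K; ++k) {
      best[k] = cap * cap;
      stopr[k] = stop_radius[k];
      bx[k] = by[k] = bz[k] = 0.0;
    }
    int active = K;
    for (size_t o = 0; o < offs.size() && active > 0; ++o) {
      double d = offs[o].d;
      // retire criteria whose spatial term alone now exceeds their best
      bool any = false;
      for (int k = 0; k < K; ++k) {
        if (stopr[k] < 0) continue;
        double s = d / dta[k];
        if (d > stopr[k] || s * s >= best[k]) { stopr[k] = -1; --active; }
        else any = true;
      }
      if (!any) break;
      double ox = step * offs[o].ix, oy = step * offs[o].iy,
             oz = step * offs[o].iz;
      double de;
      if (!trilinear(v, dgrid, org, sp, x + ox, y + oy, z + oz, &de))
        continue;
      double dd = de - dr;
      for (int k = 0; k < K; ++k) {
        if (stopr[k] < 0) continue;
        double s = d / dta[k], t = dd / dd_abs[k];
        double g2 = s * s + t * t;
        if (g2 < best[k]) { best[k] = g2; bx[k] = ox; by[k] = oy; bz[k] = oz; }
      }
    }
    // local refinement around each criterion's coarse argmin; every
    // candidate updates every criterion, so the shared-candidate nesting
    // (and with it the GPR monotonicity in criterion leniency) survives
    if (refine > 0) {
      double fstep = step / refine;
      for (int kc = 0; kc < K; ++kc) {
        if (best[kc] >= cap * cap) continue;
        for (int iz = -refine; iz <= refine; ++iz)
          for (int iy = -refine; iy <= refine; ++iy)
            for (int ix = -refine; ix <= refine; ++ix) {
              if (ix == 0 && iy == 0 && iz == 0) continue;
              double ox = bx[kc] + fstep * ix, oy = by[kc] + fstep * iy,
                     oz = bz[kc] + fstep * iz;
              double de;
              if (!trilinear(v, dgrid, org, sp, x + ox, y + oy, z + oz,
                             &de))
                continue;
              double d2 = ox * ox + oy * oy + oz * oz;
              double dd = de - dr;
              for (int k = 0; k < K; ++k) {
                double g2 = d2 / (dta[k] * dta[k]) +
                  (dd / dd_abs[k]) * (dd / dd_abs[k]);
                if (g2 < best[k]) best[k] = g2;
              }
            }
      }
    }
    for (int k = 0; k < K; ++k)
      out(i, k) = std::min(std::sqrt(best[k]), cap);
  }
  return out;
}
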