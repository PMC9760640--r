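#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Spherocylinder geometry for the colony simulator.  Cells are segments
// (the cylinder axis core, length l - d) with radius d/2.  Coordinates
// are physical (micrometres), ordered (z, y, x).

struct V3 { double z, y, x; };
static inline V3 sub(const V3& a, const V3& b) { return V3{a.z - b.z, a.y - b.y, a.x - b.x}; }
static inline V3 add(const V3& a, const V3& b) { return V3{a.z + b.z, a.y + b.y, a.x + b.x}; }
static inline V3 scl(const V3& a, double s) { return V3{a.z * s, a.y * s, a.x * s}; }
static inline double dot(const V3& a, const V3& b) { return a.z * b.z + a.y * b.y + a.x * b.x; }
static inline double nrm(const V3& a) { return std::sqrt(dot(a, a)); }

// closest points between segments p1+s*d1 (s in [0,1]) and p2+t*d2
static double seg_seg_dist(const V3& p1, const V3& d1, const V3& p2,
                           const V3& d2, double& s, double& t) {
  V3 r = sub(p1, p2);
  double a = dot(d1, d1), e = dot(d2, d2), f = dot(d2, r);
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = t = 0.0; return nrm(r); }
  if (a <= EPS) {
    s = 0.0;
    t = std::min(1.0, std::max(0.0, f / e));
  } else {
    double c = dot(d1, r);
    if (e <= EPS) {
      t = 0.0;
      s = std::min(1.0, std::max(0.0, -c / a));
    } else {
      double b = dot(d1, d2), denom = a * e - b * b;
      s = denom > EPS ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) {
        t = 0.0;
        s = std::min(1.0, std::max(0.0, -c / a));
      } else if (t > 1.0) {
        t = 1.0;
        s = std::min(1.0, std::max(0.0, (b - c) / a));
      }
    }
  }
  V3 c1 = add(p1, scl(d1, s)), c2 = add(p2, scl(d2, t));
  return nrm(sub(c1, c2));
}

// Iterative pairwise push-apart: any pair of cells whose spherocylinder
// surfaces overlap more than tol is moved apart symmetrically along the
// line joining the closest axis points.  Centroid z is kept >= d/2
// (substrate).  Returns updated centroids; attribute "converged".
// [[Rcpp::export]]
List cpp_relax(NumericMatrix centroid, NumericMatrix axis, NumericVector len,
               NumericVector diam, double tol_frac, int max_iter, double eps_push) {
  int n = centroid.nrow();
  std::vector<V3> c(n), a(n);
  for (int i = 0; i < n; i++) {
    c[i] = V3{centroid(i, 0), centroid(i, 1), centroid(i, 2)};
    a[i] = V3{axis(i, 0), axis(i, 1), axis(i, 2)};
  }
  bool converged = false;
  int it = 0;
  for (it = 0; it < max_iter; it++) {
    bool any = false;
    for (int i = 0; i < n; i++) {
      for (int j = i + 1; j < n; j++) {
        double hi = std::max(0.0, (len[i] - diam[i]) / 2.0);
        double hj = std::max(0.0, (len[j] - diam[j]) / 2.0);
        // quick reject on bounding spheres
        double rr = hi + hj + (diam[i] + diam[j]) / 2.0;
        V3 dc = sub(c[i], c[j]);
        if (dot(dc, dc) > rr * rr) continue;
        V3 p1 = sub(c[i], scl(a[i], hi)), d1 = scl(a[i], 2.0 * hi);
        V3 p2 = sub(c[j], scl(a[j], hj)), d2 = scl(a[j], 2.0 * hj);
        double s, t;
        double dist = seg_seg_dist(p1, d1, p2, d2, s, t);
        double req = (diam[i] + diam[j]) / 2.0 * (1.0 - tol_frac);
        if (dist < req) {
          any = true;
          V3 q1 = add(p1, scl(d1, s)), q2 = add(p2, scl(d2, t));
          V3 dir = sub(q1, q2);
          double dn = nrm(dir);
          if (dn < 1e-9) {
            // coincident axis points: push along a deterministic direction
            dir = V3{0.0, (i + 1) * 0.13 - (j + 1) * 0.07, 1.0};
            dn = nrm(dir);
          }
          dir = scl(dir, 1.0 / dn);
          double push = (req - dist) / 2.0 + eps_push;
          c[i] = add(c[i], scl(dir, push));
          c[j] = sub(c[j], scl(dir, push));
        }
      }
      if (c[i].z < diam[i] / 2.0) c[i].z = diam[i] / 2.0;
    }
    if (!any) { converged = true; break; }
  }
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; i++) {
    out(i, 0) = c[i].z;
    out(i, 1) = c[i].y;
    out(i, 2) = c[i].x;
  }
  return List::create(_["centroid"] = out, _["converged"] = converged,
                      _["iterations"] = it + 1);
}

// minimum pairwise surface separation (negative = overlap), for tests
// [[Rcpp::export]]
double cpp_min_separation(NumericMatrix centroid, NumericMatrix axis,
                          NumericVector len, NumericVector diam) {
  int n = centroid.nrow();
  double best = R_PosInf;
  for (int i = 0; i < n; i++)
    for (int j = i + 1; j < n; j++) {
      double hi = std::max(0.0, (len[i] - diam[i]) / 2.0);
      double hj = std::max(0.0, (len[j] - diam[j]) / 2.0);
      V3 ci{centroid(i, 0), centroid(i, 1), centroid(i, 2)};
      V3 cj{centroid(j, 0), centroid(j, 1), centroid(j, 2)};
      V3 ai{axis(i, 0), axis(i, 1), axis(i, 2)};
      V3 aj{axis(j, 0), axis(j, 1), axis(j, 2)};
      V3 p1 = sub(ci, scl(ai, hi)), d1 = scl(ai, 2.0 * hi);
      V3 p2 = sub(cj, scl(aj, hj)), d2 = scl(aj, 2.0 * hj);
      double s, t;
      double dist = seg_seg_dist(p1, d1, p2, d2, s, t);
      best = std::min(best, dist - (diam[i] + diam[j]) / 2.0);
    }
  return best;
}

// Voxelize spherocylinders: voxel centre at origin + (index + 0.5)*voxel
// (0-based index).  A voxel belongs to cell k iff its centre lies within
// radius of cell k's axis segment; ties go to the smaller axis distance,
// then to the smaller cell id.
// [[Rcpp::export]]
IntegerVector cpp_voxelize(NumericMatrix centroid, NumericMatrix axis,
                           NumericVector len, NumericVector diam,
                           IntegerVector ids, IntegerVector dim,
                           NumericVector voxel, NumericVector origin) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  std::vector<double> best(n, R_PosInf);
  int ncell = centroid.nrow();
  for (int k = 0; k < ncell; k++) {
    double r = diam[k] / 2.0;
    double h = std::max(0.0, (len[k] - diam[k]) / 2.0);
    V3 c{centroid(k, 0), centroid(k, 1), centroid(k, 2)};
    V3 a{axis(k, 0), axis(k, 1), axis(k, 2)};
    V3 e1 = sub(c, scl(a, h)), e2 = add(c, scl(a, h));
    double zlo = std::min(e1.z, e2.z) - r, zhi = std::max(e1.z, e2.z) + r;
    double ylo = std::min(e1.y, e2.y) - r, yhi = std::max(e1.y, e2.y) + r;
    double xlo = std::min(e1.x, e2.x) - r, xhi = std::max(e1.x, e2.x) + r;
    int iz0 = std::max(0, (int)std::floor((zlo - origin[0]) / voxel[0] - 0.5));
    int iz1 = std::min(nz - 1, (int)std::ceil((zhi - origin[0]) / voxel[0] - 0.5));
    int iy0 = std::max(0, (int)std::floor((ylo - origin[1]) / voxel[1] - 0.5));
    int iy1 = std::min(ny - 1, (int)std::ceil((yhi - origin[1]) / voxel[1] - 0.5));
    int ix0 = std::max(0, (int)std::floor((xlo - origin[2]) / voxel[2] - 0.5));
    int ix1 = std::min(nx - 1, (int)std::ceil((xhi - origin[2]) / voxel[2] - 0.5));
    V3 d = scl(a, 2.0 * h);
    double dd = dot(d, d);
    for (int ix = ix0; ix <= ix1; ix++)
      for (int iy = iy0; iy <= iy1; iy++)
        for (int iz = iz0; iz <= iz1; iz++) {
          V3 p{origin[0] + (iz + 0.5) * voxel[0],
               origin[1] + (iy + 0.5) * voxel[1],
               origin[2] + (ix + 0.5) * voxel[2]};
          V3 w = sub(p, e1);
          double tt = dd > 1e-15 ? std::min(1.0, std::max(0.0, dot(w, d) / dd)) : 0.0;
          V3 q = add(e1, scl(d, tt));
          double dist = nrm(sub(p, q));
          if (dist <= r) {
            R_xlen_t id = (R_xlen_t)iz + (R_xlen_t)nz * ((R_xlen_t)iy + (R_xlen_t)ny * ix);
            if (dist < best[id] - 1e-12 ||
                (std::fabs(dist - best[id]) <= 1e-12 && ids[k] < lab[id])) {
              best[id] = dist;
              lab[id] = ids[k];
            }
          }
        }
  }
  return lab;
}
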