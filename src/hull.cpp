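#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Volume of the 3D convex hull of a point cloud, by incremental
// (beneath-beyond) construction.  Used for object solidity; point sets
// are voxel corners, typically a few thousand points, so the simple
// O(n * faces) scan per insertion is adequate.

struct P3 { double x, y, z; };
static inline P3 psub(const P3& a, const P3& b) { return P3{a.x - b.x, a.y - b.y, a.z - b.z}; }
static inline P3 pcross(const P3& a, const P3& b) {
  return P3{a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double pdot(const P3& a, const P3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

struct Face { int a, b, c; bool alive; };

// [[Rcpp::export]]
double cpp_hull_volume(NumericMatrix pts) {
  int n = pts.nrow();
  if (n < 4) return 0.0;
  std::vector<P3> p(n);
  double scale = 0.0;
  for (int i = 0; i < n; i++) {
    p[i] = P3{pts(i, 0), pts(i, 1), pts(i, 2)};
    scale = std::max(scale, std::fabs(p[i].x));
    scale = std::max(scale, std::fabs(p[i].y));
    scale = std::max(scale, std::fabs(p[i].z));
  }
  double eps = 1e-9 * std::max(1.0, scale);

  // initial simplex: two extreme points, a third maximizing area, a
  // fourth maximizing volume
  int i0 = 0, i1 = 0;
  for (int i = 1; i < n; i++) {
    if (p[i].x < p[i0].x) i0 = i;
    if (p[i].x > p[i1].x) i1 = i;
  }
  if (i0 == i1) {
    for (int i = 1; i < n; i++)
      if (p[i].y != p[0].y || p[i].z != p[0].z || p[i].x != p[0].x) { i1 = i; break; }
    if (i0 == i1) return 0.0;
  }
  int i2 = -1;
  double besta = eps;
  for (int i = 0; i < n; i++) {
    P3 cr = pcross(psub(p[i1], p[i0]), psub(p[i], p[i0]));
    double a2 = std::sqrt(pdot(cr, cr));
    if (a2 > besta) { besta = a2; i2 = i; }
  }
  if (i2 < 0) return 0.0;
  int i3 = -1;
  double bestv = eps;
  P3 nrm0 = pcross(psub(p[i1], p[i0]), psub(p[i2], p[i0]));
  for (int i = 0; i < n; i++) {
    double v = std::fabs(pdot(nrm0, psub(p[i], p[i0])));
    if (v > bestv) { bestv = v; i3 = i; }
  }
  if (i3 < 0) return 0.0; // coplanar cloud

  std::vector<Face> faces;
  P3 inner{(p[i0].x + p[i1].x + p[i2].x + p[i3].x) / 4.0,
           (p[i0].y + p[i1].y + p[i2].y + p[i3].y) / 4.0,
           (p[i0].z + p[i1].z + p[i2].z + p[i3].z) / 4.0};
  auto addFace = [&](int a, int b, int c) {
    // orient so the interior point is below the face
    P3 nn = pcross(psub(p[b], p[a]), psub(p[c], p[a]));
    if (pdot(nn, psub(inner, p[a])) > 0) std::swap(b, c);
    faces.push_back(Face{a, b, c, true});
  };
  addFace(i0, i1, i2);
  addFace(i0, i1, i3);
  addFace(i0, i2, i3);
  addFace(i1, i2, i3);

  for (int i = 0; i < n; i++) {
    if (i == i0 || i == i1 || i == i2 || i == i3) continue;
    // find faces visible from p[i]
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); f++) {
      if (!faces[f].alive) continue;
      P3 nn = pcross(psub(p[faces[f].b], p[faces[f].a]),
                     psub(p[faces[f].c], p[faces[f].a]));
      if (pdot(nn, psub(p[i], p[faces[f].a])) > eps) vis.push_back((int)f);
    }
    if (vis.empty()) continue;
    // horizon: edges belonging to exactly one visible face
    std::vector<std::pair<int, int> > edges;
    for (int fi : vis) {
      const Face& f = faces[fi];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int k = 0; k < 3; k++) {
        std::pair<int, int> rev(e[k][1], e[k][0]);
        bool cancelled = false;
        for (size_t m = 0; m < edges.size(); m++)
          if (edges[m] == rev) {
            edges.erase(edges.begin() + m);
            cancelled = true;
            break;
          }
        if (!cancelled) edges.push_back(std::make_pair(e[k][0], e[k][1]));
      }
    }
    for (int fi : vis) faces[fi].alive = false;
    for (size_t m = 0; m < edges.size(); m++) {
      // new face keeps the winding of the horizon edge so orientation
      // stays outward
      faces.push_back(Face{edges[m].first, edges[m].second, i, true});
    }
  }

  double vol = 0.0;
  for (size_t f = 0; f < faces.size(); f++) {
    if (!faces[f].alive) continue;
    P3 a = psub(p[faces[f].a], inner);
    P3 b = psub(p[faces[f].b], inner);
    P3 c = psub(p[faces[f].c], inner);
    vol += std::fabs(pdot(a, pcross(b, c))) / 6.0;
  }
  return vol;
}
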