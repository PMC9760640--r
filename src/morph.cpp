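#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
using namespace Rcpp;

// Voxel-level primitives for 3D volumes stored as R arrays dim
// c(nz, ny, nx), column-major: index = z + nz*(y + ny*x).

static inline R_xlen_t vidx(int z, int y, int x, int nz, int ny) {
  return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
}

// ---- separable Gaussian blur, zero padding outside the volume --------------

static void conv1d_axis(std::vector<double>& vol, int nz, int ny, int nx,
                        const std::vector<double>& k, int axis) {
  int half = (int)k.size() / 2;
  int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(len), res(len);
  int n1 = axis == 0 ? ny : nz;
  int n2 = axis == 0 ? nx : (axis == 1 ? nx : ny);
  for (int a = 0; a < n1; a++)
    for (int b = 0; b < n2; b++) {
      for (int i = 0; i < len; i++) {
        R_xlen_t id = axis == 0 ? vidx(i, a, b, nz, ny)
                    : axis == 1 ? vidx(a, i, b, nz, ny)
                                : vidx(a, b, i, nz, ny);
        line[i] = vol[id];
      }
      for (int i = 0; i < len; i++) {
        double s = 0.0;
        for (int j = -half; j <= half; j++) {
          int p = i + j;
          if (p >= 0 && p < len) s += line[p] * k[j + half];
        }
        res[i] = s;
      }
      for (int i = 0; i < len; i++) {
        R_xlen_t id = axis == 0 ? vidx(i, a, b, nz, ny)
                    : axis == 1 ? vidx(a, i, b, nz, ny)
                                : vidx(a, b, i, nz, ny);
        vol[id] = res[i];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_gaussian_blur(NumericVector x, IntegerVector dim,
                                NumericVector sigma, int ksize) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  std::vector<double> vol(x.begin(), x.end());
  int half = ksize / 2;
  for (int axis = 0; axis < 3; axis++) {
    double s = sigma[axis];
    std::vector<double> k(ksize);
    double tot = 0.0;
    for (int j = -half; j <= half; j++) {
      double w = (s <= 0) ? (j == 0 ? 1.0 : 0.0)
                          : std::exp(-0.5 * (double)j * j / (s * s));
      k[j + half] = w;
      tot += w;
    }
    for (int j = 0; j < ksize; j++) k[j] /= tot;
    conv1d_axis(vol, nz, ny, nx, k, axis);
  }
  NumericVector out(vol.begin(), vol.end());
  return out;
}

// ---- separable box min/max filter (grayscale erosion/dilation) -------------
// Neighbourhood is the axis-aligned box of half-width `radius`; voxels
// outside the volume are ignored (border values replicate implicitly).

static void minmax1d_axis(std::vector<double>& vol, int nz, int ny, int nx,
                          int radius, int axis, bool do_max) {
  int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  std::vector<double> line(len), res(len);
  int n1 = axis == 0 ? ny : nz;
  int n2 = axis == 0 ? nx : (axis == 1 ? nx : ny);
  for (int a = 0; a < n1; a++)
    for (int b = 0; b < n2; b++) {
      for (int i = 0; i < len; i++) {
        R_xlen_t id = axis == 0 ? vidx(i, a, b, nz, ny)
                    : axis == 1 ? vidx(a, i, b, nz, ny)
                                : vidx(a, b, i, nz, ny);
        line[i] = vol[id];
      }
      for (int i = 0; i < len; i++) {
        int lo = std::max(0, i - radius), hi = std::min(len - 1, i + radius);
        double m = line[lo];
        for (int p = lo + 1; p <= hi; p++)
          m = do_max ? std::max(m, line[p]) : std::min(m, line[p]);
        res[i] = m;
      }
      for (int i = 0; i < len; i++) {
        R_xlen_t id = axis == 0 ? vidx(i, a, b, nz, ny)
                    : axis == 1 ? vidx(a, i, b, nz, ny)
                                : vidx(a, b, i, nz, ny);
        vol[id] = res[i];
      }
    }
}

// [[Rcpp::export]]
NumericVector cpp_box_filter(NumericVector x, IntegerVector dim, int radius,
                             bool do_max) {
  std::vector<double> vol(x.begin(), x.end());
  for (int axis = 0; axis < 3; axis++)
    minmax1d_axis(vol, dim[0], dim[1], dim[2], radius, axis, do_max);
  NumericVector out(vol.begin(), vol.end());
  return out;
}

// ---- 6-connected component labelling ---------------------------------------

// [[Rcpp::export]]
IntegerVector cpp_label6(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  std::vector<R_xlen_t> stack;
  int next = 0;
  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++) {
        R_xlen_t id = vidx(z, y, x, nz, ny);
        if (mask[id] == 0 || lab[id] != 0) continue;
        next++;
        lab[id] = next;
        stack.push_back(id);
        while (!stack.empty()) {
          R_xlen_t cur = stack.back();
          stack.pop_back();
          int cz = (int)(cur % nz);
          int cy = (int)((cur / nz) % ny);
          int cx = (int)(cur / ((R_xlen_t)nz * ny));
          for (int d = 0; d < 6; d++) {
            int pz = cz + dz[d], py = cy + dy[d], px = cx + dx[d];
            if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx)
              continue;
            R_xlen_t pid = vidx(pz, py, px, nz, ny);
            if (mask[pid] != 0 && lab[pid] == 0) {
              lab[pid] = next;
              stack.push_back(pid);
            }
          }
        }
      }
  return lab;
}

// ---- seeded watershed (priority flood, 6-connectivity) ---------------------
// Regions grow from seed labels over the elevation map, restricted to the
// mask.  Deterministic: ties in elevation are broken by insertion order.

struct WsNode {
  double elev;
  unsigned long long order;
  R_xlen_t idx;
};
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;
    return a.order > b.order;
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector elev, IntegerVector seeds,
                            IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(n);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  unsigned long long order = 0;
  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};

  for (R_xlen_t i = 0; i < n; i++)
    if (seeds[i] != 0 && mask[i] != 0) {
      lab[i] = seeds[i];
      pq.push(WsNode{elev[i], order++, i});
    }
  while (!pq.empty()) {
    WsNode nd = pq.top();
    pq.pop();
    R_xlen_t cur = nd.idx;
    int cz = (int)(cur % nz);
    int cy = (int)((cur / nz) % ny);
    int cx = (int)(cur / ((R_xlen_t)nz * ny));
    int curlab = lab[cur];
    for (int d = 0; d < 6; d++) {
      int pz = cz + dz[d], py = cy + dy[d], px = cx + dx[d];
      if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx)
        continue;
      R_xlen_t pid = vidx(pz, py, px, nz, ny);
      if (mask[pid] != 0 && lab[pid] == 0) {
        lab[pid] = curlab;
        pq.push(WsNode{elev[pid], order++, pid});
      }
    }
  }
  return lab;
}

// ---- boundary voxels (6-connectivity, out-of-volume faces ignored) ---------
// A voxel is a boundary voxel of its object if at least one in-volume face
// neighbour carries a different label.  Faces at the volume edge are not
// counted, so objects clipped by the field of view gain no artificial
// boundary there.

// [[Rcpp::export]]
LogicalVector cpp_boundary6(IntegerVector lab, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  LogicalVector out(n);
  const int dz[6] = {-1, 1, 0, 0, 0, 0};
  const int dy[6] = {0, 0, -1, 1, 0, 0};
  const int dx[6] = {0, 0, 0, 0, -1, 1};
  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++)
      for (int z = 0; z < nz; z++) {
        R_xlen_t id = vidx(z, y, x, nz, ny);
        if (lab[id] == 0) continue;
        bool bnd = false;
        for (int d = 0; d < 6 && !bnd; d++) {
          int pz = z + dz[d], py = y + dy[d], px = x + dx[d];
          if (pz < 0 || pz >= nz || py < 0 || py >= ny || px < 0 || px >= nx)
            continue;
          if (lab[vidx(pz, py, px, nz, ny)] != lab[id]) bnd = true;
        }
        out[id] = bnd;
      }
  return out;
}
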