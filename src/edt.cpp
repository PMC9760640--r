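#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher 1D
// parabola method applied per axis), computed as squared distances so
// results are exact integers on voxel grids.  Returns, for every voxel,
// the squared distance to the nearest voxel with mask value 0.
// Volumes are R arrays dim c(nz, ny, nx), column-major:
// index = z + nz*(y + ny*x).
//
// "No feature" is encoded by a sentinel much larger than any attainable
// squared distance; real parabolas always dominate sentinel ones, so the
// sentinel never perturbs finite results.

static const double BIG = 1e15;

static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (k > 0 && s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(IntegerVector mask, IntegerVector dim) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = mask[i] == 0 ? 0.0 : BIG;

  int maxdim = std::max(nz, std::max(ny, nx));
  std::vector<double> f(maxdim), d(maxdim), z(maxdim + 1);
  std::vector<int> v(maxdim);

  for (int x = 0; x < nx; x++)
    for (int y = 0; y < ny; y++) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int zz = 0; zz < nz; zz++) f[zz] = out[base + zz];
      dt1d(f, d, v, z, nz);
      for (int zz = 0; zz < nz; zz++) out[base + zz] = d[zz];
    }
  for (int x = 0; x < nx; x++)
    for (int zz = 0; zz < nz; zz++) {
      for (int y = 0; y < ny; y++)
        f[y] = out[zz + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(f, d, v, z, ny);
      for (int y = 0; y < ny; y++)
        out[zz + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = d[y];
    }
  for (int y = 0; y < ny; y++)
    for (int zz = 0; zz < nz; zz++) {
      for (int x = 0; x < nx; x++)
        f[x] = out[zz + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)];
      dt1d(f, d, v, z, nx);
      for (int x = 0; x < nx; x++)
        out[zz + (R_xlen_t)nz * (y + (R_xlen_t)ny * x)] = d[x];
    }
  // anything at sentinel scale means "no zero voxel anywhere"
  for (R_xlen_t i = 0; i < n; i++)
    if (out[i] >= BIG / 2) out[i] = R_PosInf;
  return out;
}
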