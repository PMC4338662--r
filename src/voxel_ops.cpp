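#include <Rcpp.h>
#include <vector>
#include <limits>
#include <cmath>

using namespace Rcpp;

// "Infinity" that stays finite so parabola intersections never produce
// NaN; adding any realistic squared distance leaves it unchanged in
// double precision.
static const double BIG = 1e300;

// Exact 1D squared distance transform (lower envelope of parabolas),
// sample positions x_i = i * w.
static void dt1d(const double* f, double* out, int n, double w,
                 std::vector<int>& v, std::vector<double>& z,
                 std::vector<double>& x) {
  const double INF = std::numeric_limits<double>::infinity();
  for (int i = 0; i < n; ++i) x[i] = i * w;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double num = (f[q] + x[q] * x[q]) - (f[v[k]] + x[v[k]] * x[v[k]]);
      s = num / (2.0 * x[q] - 2.0 * x[v[k]]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < x[q]) ++k;
    double d = x[q] - x[v[k]];
    out[q] = d * d + f[v[k]];
  }
}

// Anisotropic squared Euclidean distance transform of a 3D mask.
// Distance from every voxel centre to the nearest TRUE voxel centre,
// with per-axis physical spacing.  Column-major (R) layout.
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector d(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) d[i] = mask[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), out(nmax), z(nmax + 1), x(nmax);
  std::vector<int> v(nmax);

  // pass along x (stride 1)
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      bool any = false;
      for (int i = 0; i < nx; ++i) { f[i] = d[base + i]; if (f[i] < BIG) any = true; }
      if (!any) continue;
      dt1d(f.data(), out.data(), nx, spacing[0], v, z, x);
      for (int i = 0; i < nx; ++i) d[base + i] = out[i];
    }
  // pass along y (stride nx)
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * ny * k;
      bool any = false;
      for (int j = 0; j < ny; ++j) { f[j] = d[base + (R_xlen_t)nx * j]; if (f[j] < BIG) any = true; }
      if (!any) continue;
      dt1d(f.data(), out.data(), ny, spacing[1], v, z, x);
      for (int j = 0; j < ny; ++j) d[base + (R_xlen_t)nx * j] = out[j];
    }
  // pass along z (stride nx*ny)
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = i + (R_xlen_t)nx * j;
      bool any = false;
      for (int k = 0; k < nz; ++k) { f[k] = d[base + sz * k]; if (f[k] < BIG) any = true; }
      if (!any) continue;
      dt1d(f.data(), out.data(), nz, spacing[2], v, z, x);
      for (int k = 0; k < nz; ++k) d[base + sz * k] = out[k];
    }
  return d;
}

// Connected-component labelling under 26-adjacency.  Voxels belong to the
// same component iff they share the same input label and are 26-connected.
// Returns component ids 1..n_comp (0 = background).
// [[Rcpp::export]]
IntegerVector cpp_label26(IntegerVector labels, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector comp(ntot);
  std::fill(comp.begin(), comp.end(), 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t s = 0; s < ntot; ++s) {
    if (labels[s] == 0 || comp[s] != 0) continue;
    ++next;
    const int lab = labels[s];
    comp[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int ci = cur % nx;
      int cj = (cur / nx) % ny;
      int ck = cur / ((R_xlen_t)nx * ny);
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            int ii = ci + di, jj = cj + dj, kk = ck + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t nb = ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
            if (labels[nb] == lab && comp[nb] == 0) {
              comp[nb] = next;
              stack.push_back(nb);
            }
          }
    }
  }
  return comp;
}

// Index (1-based) of the nearest of m reference points for each of n query
// points, plain all-pairs scan.  Ties resolved to the lowest index.
// [[Rcpp::export]]
IntegerVector cpp_nearest_point(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow();
  IntegerVector idx(n);
  for (int i = 0; i < n; ++i) {
    double best = std::numeric_limits<double>::infinity();
    int bj = 1;
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    for (int j = 0; j < m; ++j) {
      double dx = qx - ref(j, 0), dy = qy - ref(j, 1), dz = qz - ref(j, 2);
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j + 1; }
    }
    idx[i] = bj;
  }
  return idx;
}
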