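#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher lower
// envelope of parabolas), separable over the three axes, with per-axis
// physical spacing so distances come out in mm (or voxel units if spacing=1).

static void dt1d(const std::vector<double> &f, std::vector<double> &d,
                 double w2, int n) {
  static thread_local std::vector<int> v;
  static thread_local std::vector<double> zb;
  v.assign(n, 0); zb.assign(n + 1, 0.0);
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF && k == 0) { v[0] = q; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + (double)q*q*w2) - (f[p] + (double)p*p*w2)) /
          (2.0 * w2 * (q - p));
      if (s <= zb[k]) { --k; } else break;
    }
    ++k;
    v[k] = q; zb[k] = s; zb[k+1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (zb[k+1] < q) ++k;
    double dq = (double)(q - v[k]);
    d[q] = dq * dq * w2 + f[v[k]];
  }
}

// mask: logical/integer array, 1 marks the source set (distance 0).
// [[Rcpp::export(name = ".edt3")]]
NumericVector edt3(LogicalVector mask, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> g(N);
  for (R_xlen_t i = 0; i < N; ++i) g[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // x pass
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, spacing[0]*spacing[0], nx);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // y pass
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * ny * (R_xlen_t)k;
      for (int j = 0; j < ny; ++j) f[j] = g[base + (R_xlen_t)nx * j];
      dt1d(f, d, spacing[1]*spacing[1], ny);
      for (int j = 0; j < ny; ++j) g[base + (R_xlen_t)nx * j] = d[j];
    }
  // z pass
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)i + (R_xlen_t)nx * j;
      R_xlen_t stride = (R_xlen_t)nx * ny;
      for (int k = 0; k < nz; ++k) f[k] = g[base + stride * k];
      dt1d(f, d, spacing[2]*spacing[2], nz);
      for (int k = 0; k < nz; ++k) g[base + stride * k] = d[k];
    }

  NumericVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// 6- or 26-connected component labelling of a binary 3D array.
// Labels are assigned in scan order (deterministic); 0 = background.
// [[Rcpp::export(name = ".labelComponents3")]]
IntegerVector labelComponents3(LogicalVector mask, IntegerVector dims,
                               int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(N);
  std::vector<R_xlen_t> stack;
  int next = 0;
  std::vector<int> offs;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh != 1) continue;
        offs.push_back(dx); offs.push_back(dy); offs.push_back(dz);
      }
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++next;
    stack.clear(); stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int i = (int)(cur % nx), j = (int)((cur / nx) % ny), k = (int)(cur / ((R_xlen_t)nx*ny));
      for (size_t o = 0; o < offs.size(); o += 3) {
        int ii = i + offs[o], jj = j + offs[o+1], kk = k + offs[o+2];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz) continue;
        R_xlen_t q = (R_xlen_t)ii + (R_xlen_t)nx * (jj + (R_xlen_t)ny * kk);
        if (mask[q] && !lab[q]) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}
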