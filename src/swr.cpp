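#include <Rcpp.h>
using namespace Rcpp;

// Spatial weight-smoothing: penalty and gradient in one pass.  W is N x k
// (voxels x hidden units); each column is a 3D field over dims.  Forward
// finite differences with replicated edges (boundary difference 0); the
// factor 2 accounts for the tied output layer sharing the weights.
// [[Rcpp::export(name = ".swrGradC")]]
List swrGradC(NumericMatrix W, IntegerVector dims, bool wantGrad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t N = (R_xlen_t)nx * ny * nz;
  const int k = W.ncol();
  if ((R_xlen_t)W.nrow() != N) stop("W rows do not match dims");
  NumericMatrix G;
  if (wantGrad) G = NumericMatrix(N, k);
  double pen = 0.0;
  for (int j = 0; j < k; ++j) {
    const double *w = &W(0, j);
    double *g = wantGrad ? &G(0, j) : (double *)0;
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t i = (R_xlen_t)x + (R_xlen_t)nx * (y + (R_xlen_t)ny * z);
          // +x, +y, +z forward differences
          if (x + 1 < nx) {
            double d = w[i + 1] - w[i];
            pen += d * d;
            if (g) { g[i] -= 4 * d; g[i + 1] += 4 * d; }
          }
          if (y + 1 < ny) {
            double d = w[i + nx] - w[i];
            pen += d * d;
            if (g) { g[i] -= 4 * d; g[i + nx] += 4 * d; }
          }
          if (z + 1 < nz) {
            double d = w[i + (R_xlen_t)nx * ny] - w[i];
            pen += d * d;
            if (g) { g[i] -= 4 * d; g[i + (R_xlen_t)nx * ny] += 4 * d; }
          }
        }
  }
  return List::create(_["penalty"] = 2.0 * pen,
                      _["grad"] = wantGrad ? (SEXP)G : R_NilValue);
}

// In-place Adam update: p, m, v are modified directly (callers must own
// them exclusively).  b1t/b2t are beta1^t / beta2^t for bias correction.
// [[Rcpp::export(name = ".adamStepC")]]
void adamStepC(NumericVector p, NumericVector m, NumericVector v,
               NumericVector g, double lr, double b1, double b2,
               double b1t, double b2t, double eps) {
  const R_xlen_t n = p.size();
  if (m.size() != n || v.size() != n || g.size() != n)
    stop("adam buffers must match the parameter size");
  double *pp = REAL(p), *pm = REAL(m), *pv = REAL(v);
  const double *pg = REAL(g);
  const double c1 = 1.0 - b1, c2 = 1.0 - b2;
  const double k1 = 1.0 / (1.0 - b1t), k2 = 1.0 / (1.0 - b2t);
  for (R_xlen_t i = 0; i < n; ++i) {
    double mi = b1 * pm[i] + c1 * pg[i];
    double vi = b2 * pv[i] + c2 * pg[i] * pg[i];
    pm[i] = mi; pv[i] = vi;
    pp[i] -= lr * (mi * k1) / (std::sqrt(vi * k2) + eps);
  }
}
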