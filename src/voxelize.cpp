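#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Scanline voxelization: for every (x, y) voxel-column a ray is cast along +z
// through the column's (slightly jittered) center, triangle crossings are
// collected, and voxel centers falling inside an odd crossing interval are
// marked occupied.  The jitter (a fixed, deterministic fraction of the voxel
// pitch) keeps rays in general position with respect to mesh edges/vertices,
// which is what makes pure parity counting robust for watertight meshes.

static const double JITTER = 0.4142135623730951e-3; // fixed fraction of pitch

// [[Rcpp::export(name = ".voxelizeMesh")]]
LogicalVector voxelizeMesh(NumericMatrix V, IntegerMatrix F,
                           NumericVector xs, NumericVector ys,
                           NumericVector zs) {
  const int nx = xs.size(), ny = ys.size(), nz = zs.size();
  const double dx = nx > 1 ? xs[1] - xs[0] : 1.0;
  const double dy = ny > 1 ? ys[1] - ys[0] : 1.0;
  const double ex = JITTER * dx, ey = JITTER * dy * 0.7310585786;

  std::vector< std::vector<double> > crossings((size_t)nx * ny);
  const int nF = F.nrow();
  for (int t = 0; t < nF; ++t) {
    const int a = F(t,0)-1, b = F(t,1)-1, c = F(t,2)-1;
    const double ax = V(a,0), ay = V(a,1), az = V(a,2);
    const double bx = V(b,0), by = V(b,1), bz = V(b,2);
    const double cx = V(c,0), cy = V(c,1), cz = V(c,2);
    double xmin = std::min(ax, std::min(bx, cx));
    double xmax = std::max(ax, std::max(bx, cx));
    double ymin = std::min(ay, std::min(by, cy));
    double ymax = std::max(ay, std::max(by, cy));
    int i0 = (int)std::ceil((xmin - ex - xs[0]) / dx);
    int i1 = (int)std::floor((xmax - ex - xs[0]) / dx);
    int j0 = (int)std::ceil((ymin - ey - ys[0]) / dy);
    int j1 = (int)std::floor((ymax - ey - ys[0]) / dy);
    if (i0 < 0) i0 = 0; if (i1 >= nx) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 >= ny) j1 = ny - 1;
    for (int j = j0; j <= j1; ++j) {
      const double py = ys[j] + ey;
      for (int i = i0; i <= i1; ++i) {
        const double px = xs[i] + ex;
        // 2D orientation tests in the xy-plane
        double w0 = (bx-ax)*(py-ay) - (by-ay)*(px-ax);
        double w1 = (cx-bx)*(py-by) - (cy-by)*(px-bx);
        double w2 = (ax-cx)*(py-cy) - (ay-cy)*(px-cx);
        bool inside = (w0 > 0 && w1 > 0 && w2 > 0) ||
                      (w0 < 0 && w1 < 0 && w2 < 0);
        if (!inside) continue;
        double area = w0 + w1 + w2;
        // barycentric interpolation of z at (px, py)
        double z = (w1 * az + w2 * bz + w0 * cz) / area;
        crossings[(size_t)i + (size_t)nx * j].push_back(z);
      }
    }
  }

  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      std::vector<double> &cz = crossings[(size_t)i + (size_t)nx * j];
      if (cz.empty()) continue;
      std::sort(cz.begin(), cz.end());
      size_t p = 0;
      for (int k = 0; k < nz; ++k) {
        const double zq = zs[k];
        while (p < cz.size() && cz[p] < zq) ++p;
        if (p & 1) out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = true;
      }
    }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// Parity test for arbitrary query points against a triangle mesh, with a 2D
// bucket grid over (x, y) so each ray only visits candidate triangles.
// [[Rcpp::export(name = ".pointsInMesh")]]
LogicalVector pointsInMesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  const int nP = P.nrow(), nF = F.nrow();
  LogicalVector out(nP);
  if (nP == 0 || nF == 0) return out;
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int v = 0; v < V.nrow(); ++v) {
    xmin = std::min(xmin, V(v,0)); xmax = std::max(xmax, V(v,0));
    ymin = std::min(ymin, V(v,1)); ymax = std::max(ymax, V(v,1));
  }
  int nb = std::max(1, (int)std::sqrt((double)nF / 4.0));
  const double bx = (xmax - xmin) / nb + 1e-12, by = (ymax - ymin) / nb + 1e-12;
  std::vector< std::vector<int> > buckets((size_t)nb * nb);
  auto clampi = [&](int v) { return std::max(0, std::min(nb - 1, v)); };
  for (int t = 0; t < nF; ++t) {
    double txmin = R_PosInf, txmax = R_NegInf, tymin = R_PosInf, tymax = R_NegInf;
    for (int e = 0; e < 3; ++e) {
      int v = F(t,e)-1;
      txmin = std::min(txmin, V(v,0)); txmax = std::max(txmax, V(v,0));
      tymin = std::min(tymin, V(v,1)); tymax = std::max(tymax, V(v,1));
    }
    int i0 = clampi((int)((txmin - xmin) / bx)), i1 = clampi((int)((txmax - xmin) / bx));
    int j0 = clampi((int)((tymin - ymin) / by)), j1 = clampi((int)((tymax - ymin) / by));
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i)
        buckets[(size_t)i + (size_t)nb * j].push_back(t);
  }
  const double ex = JITTER * bx, ey = JITTER * by * 0.7310585786;
  for (int p = 0; p < nP; ++p) {
    const double px = P(p,0) + ex, py = P(p,1) + ey, pz = P(p,2);
    if (px < xmin || px > xmax || py < ymin || py > ymax) continue;
    int bi = clampi((int)((px - xmin) / bx)), bj = clampi((int)((py - ymin) / by));
    int cnt = 0;
    for (int t : buckets[(size_t)bi + (size_t)nb * bj]) {
      const int a = F(t,0)-1, b = F(t,1)-1, c = F(t,2)-1;
      const double ax = V(a,0), ay = V(a,1), az = V(a,2);
      const double bx2 = V(b,0), by2 = V(b,1), bz = V(b,2);
      const double cx = V(c,0), cy = V(c,1), cz = V(c,2);
      double w0 = (bx2-ax)*(py-ay) - (by2-ay)*(px-ax);
      double w1 = (cx-bx2)*(py-by2) - (cy-by2)*(px-bx2);
      double w2 = (ax-cx)*(py-cy) - (ay-cy)*(px-cx);
      bool inside = (w0 > 0 && w1 > 0 && w2 > 0) ||
                    (w0 < 0 && w1 < 0 && w2 < 0);
      if (!inside) continue;
      double area = w0 + w1 + w2;
      double z = (w1 * az + w2 * bz + w0 * cz) / area;
      if (z > pz) ++cnt;
    }
    out[p] = (cnt & 1) != 0;
  }
  return out;
}
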