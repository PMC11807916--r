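#include <Rcpp.h>
#include <unordered_map>
#include <functional>
#include <cstdint>
using namespace Rcpp;

// Iso-surface extraction by marching tetrahedra on a Kuhn (6-tet) cube
// subdivision.  The Kuhn split orients every face diagonal from the
// lexicographically lowest to the highest corner of the face, so the
// triangulation is consistent across neighbouring cells and the extracted
// surface is watertight away from the sampling-domain boundary.

static inline uint64_t edge_key(uint64_t a, uint64_t b, uint64_t n) {
  if (a > b) std::swap(a, b);
  return a * n + b;
}

// [[Rcpp::export(name = ".marchingTets")]]
List marchingTets(NumericVector values, IntegerVector dims,
                  NumericVector xs, NumericVector ys, NumericVector zs,
                  double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const uint64_t N = (uint64_t)nx * ny * nz;
  if ((uint64_t)values.size() != N) stop("field size does not match dims");

  // signed field relative to iso; exact hits nudged outside (deterministic)
  std::vector<double> f(N);
  for (uint64_t i = 0; i < N; ++i) {
    double v = values[i] - iso;
    f[i] = (v == 0.0) ? 1e-12 : v;
  }

  auto lin = [&](int i, int j, int k) -> uint64_t {
    return (uint64_t)i + (uint64_t)nx * ((uint64_t)j + (uint64_t)ny * k);
  };
  auto coord = [&](int i, int j, int k, double *out) {
    out[0] = xs[i]; out[1] = ys[j]; out[2] = zs[k];
  };

  // the six permutations of axis insertion order (Kuhn path simplices)
  static const int perms[6][3] = {
    {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};

  std::unordered_map<uint64_t, int> vmap;
  std::vector<double> V;   // vertex coords, flat xyz
  std::vector<int> Fc;     // faces, flat (0-based)
  V.reserve(4096); Fc.reserve(4096);

  // interpolated vertex on the grid edge (g1, g2); canonical order g1 < g2
  auto edge_vertex = [&](uint64_t g1, int c1[3], uint64_t g2, int c2[3]) -> int {
    const int *ca = c1, *cb = c2;
    uint64_t ga = g1, gb = g2;
    if (ga > gb) { std::swap(ga, gb); std::swap(ca, cb); }
    uint64_t key = ga * N + gb;
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = f[ga], fb = f[gb];
    double t = fa / (fa - fb);
    double pa[3], pb[3];
    coord(ca[0], ca[1], ca[2], pa);
    coord(cb[0], cb[1], cb[2], pb);
    int idx = (int)(V.size() / 3);
    for (int d = 0; d < 3; ++d) V.push_back(pa[d] + t * (pb[d] - pa[d]));
    vmap.emplace(key, idx);
    return idx;
  };

  auto push_tri = [&](int a, int b, int c,
                      const double refIn[3], const double refOut[3]) {
    // orient the triangle so its normal points toward the outside (f > 0)
    double *p0 = &V[3*a], *p1 = &V[3*b], *p2 = &V[3*c];
    double u[3], w[3], n[3];
    for (int d = 0; d < 3; ++d) { u[d] = p1[d]-p0[d]; w[d] = p2[d]-p0[d]; }
    n[0] = u[1]*w[2]-u[2]*w[1];
    n[1] = u[2]*w[0]-u[0]*w[2];
    n[2] = u[0]*w[1]-u[1]*w[0];
    double dot = 0;
    for (int d = 0; d < 3; ++d) dot += n[d]*(refOut[d]-refIn[d]);
    if (dot < 0) std::swap(b, c);
    Fc.push_back(a); Fc.push_back(b); Fc.push_back(c);
  };

  int corners[4][3];
  uint64_t glin[4];
  double fv[4];

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        for (int p = 0; p < 6; ++p) {
          int cur[3] = {i, j, k};
          for (int c = 0; c < 4; ++c) {
            corners[c][0] = cur[0]; corners[c][1] = cur[1]; corners[c][2] = cur[2];
            glin[c] = lin(cur[0], cur[1], cur[2]);
            fv[c] = f[glin[c]];
            if (c < 3) cur[perms[p][c]] += 1;
          }
          int in[4], out[4], nin = 0, nout = 0;
          for (int c = 0; c < 4; ++c) {
            if (fv[c] < 0) in[nin++] = c; else out[nout++] = c;
          }
          if (nin == 0 || nin == 4) continue;
          // reference centroids for orientation
          double cin[3] = {0,0,0}, cout[3] = {0,0,0}, pc[3];
          for (int c = 0; c < nin; ++c) {
            coord(corners[in[c]][0], corners[in[c]][1], corners[in[c]][2], pc);
            for (int d = 0; d < 3; ++d) cin[d] += pc[d] / nin;
          }
          for (int c = 0; c < nout; ++c) {
            coord(corners[out[c]][0], corners[out[c]][1], corners[out[c]][2], pc);
            for (int d = 0; d < 3; ++d) cout[d] += pc[d] / nout;
          }
          if (nin == 1 || nin == 3) {
            int a = (nin == 1) ? in[0] : out[0];
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != a) o[m++] = c;
            int v0 = edge_vertex(glin[a], corners[a], glin[o[0]], corners[o[0]]);
            int v1 = edge_vertex(glin[a], corners[a], glin[o[1]], corners[o[1]]);
            int v2 = edge_vertex(glin[a], corners[a], glin[o[2]], corners[o[2]]);
            push_tri(v0, v1, v2, cin, cout);
          } else { // 2 in, 2 out -> quad
            int a = in[0], b = in[1], c0 = out[0], d0 = out[1];
            int vac = edge_vertex(glin[a], corners[a], glin[c0], corners[c0]);
            int vad = edge_vertex(glin[a], corners[a], glin[d0], corners[d0]);
            int vbc = edge_vertex(glin[b], corners[b], glin[c0], corners[c0]);
            int vbd = edge_vertex(glin[b], corners[b], glin[d0], corners[d0]);
            push_tri(vac, vad, vbd, cin, cout);
            push_tri(vac, vbd, vbc, cin, cout);
          }
        }
      }

  int nV = (int)(V.size() / 3), nF = (int)(Fc.size() / 3);
  NumericMatrix verts(nV, 3);
  for (int v = 0; v < nV; ++v)
    for (int d = 0; d < 3; ++d) verts(v, d) = V[3*v + d];
  IntegerMatrix faces(nF, 3);
  for (int t = 0; t < nF; ++t)
    for (int d = 0; d < 3; ++d) faces(t, d) = Fc[3*t + d] + 1;
  return List::create(_["vertices"] = verts, _["faces"] = faces);
}

// Connected components of a triangle mesh (faces sharing a vertex are in the
// same component).  Returns a 1-based component label per face.
// [[Rcpp::export(name = ".meshFaceComponents")]]
IntegerVector meshFaceComponents(IntegerMatrix faces, int nVertices) {
  std::vector<int> parent(nVertices);
  for (int i = 0; i < nVertices; ++i) parent[i] = i;
  std::function<int(int)> find = [&](int x) {
    while (parent[x] != x) { parent[x] = parent[parent[x]]; x = parent[x]; }
    return x;
  };
  int nF = faces.nrow();
  for (int t = 0; t < nF; ++t) {
    int a = find(faces(t,0)-1), b = find(faces(t,1)-1), c = find(faces(t,2)-1);
    parent[a] = b < a ? b : a; // union by index keeps labels deterministic
    int r = find(a);
    parent[find(b)] = r; parent[find(c)] = r;
  }
  std::unordered_map<int,int> relabel;
  IntegerVector out(nF);
  int next = 0;
  for (int t = 0; t < nF; ++t) {
    int r = find(faces(t,0)-1);
    auto it = relabel.find(r);
    if (it == relabel.end()) { relabel.emplace(r, ++next); out[t] = next; }
    else out[t] = it->second;
  }
  return out;
}

// Closedness check: every undirected edge must be shared by exactly 2 faces.
// Returns list(closed, nEdges, maxEdgeCount).
// [[Rcpp::export(name = ".meshEdgeAudit")]]
List meshEdgeAudit(IntegerMatrix faces, int nVertices) {
  std::unordered_map<uint64_t, int> counts;
  uint64_t n = (uint64_t)nVertices + 1;
  int nF = faces.nrow();
  counts.reserve((size_t)nF * 2);
  for (int t = 0; t < nF; ++t) {
    int v[3] = {faces(t,0), faces(t,1), faces(t,2)};
    for (int e = 0; e < 3; ++e)
      counts[edge_key(v[e], v[(e+1)%3], n)] += 1;
  }
  bool closed = true;
  int mx = 0;
  for (auto &kv : counts) {
    if (kv.second != 2) closed = false;
    if (kv.second > mx) mx = kv.second;
  }
  return List::create(_["closed"] = closed,
                      _["nEdges"] = (double)counts.size(),
                      _["maxEdgeCount"] = mx);
}
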