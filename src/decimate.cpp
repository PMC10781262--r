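#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>
using namespace Rcpp;

namespace {

struct EdgeItem {
  double len;
  int u, v;      // u < v
  int vu, vv;    // vertex versions at push time (lazy invalidation)
};

struct LongerFirst {
  bool operator()(const EdgeItem &a, const EdgeItem &b) const {
    return a.len > b.len;
  }
};

}  // namespace

// Iterative shortest-edge collapse with midpoint placement.
// Collapses one vertex per step until the number of live vertices is at most
// `target`. Faces that lose a vertex pair or become degenerate are dropped.
// Stale priority-queue entries are skipped via per-vertex version counters.
// [[Rcpp::export]]
List collapse_decimate(NumericMatrix verts, IntegerMatrix faces, int target) {
  const int nv = verts.nrow();
  const int nf = faces.nrow();
  std::vector<double> X(nv), Y(nv), Z(nv);
  for (int i = 0; i < nv; ++i) {
    X[i] = verts(i, 0);
    Y[i] = verts(i, 1);
    Z[i] = verts(i, 2);
  }
  std::vector<std::array<int, 3>> F(nf);
  std::vector<char> fAlive(nf, 1), vAlive(nv, 1);
  std::vector<int> version(nv, 0);
  std::vector<std::vector<int>> vf(nv);
  for (int t = 0; t < nf; ++t) {
    for (int k = 0; k < 3; ++k) {
      F[t][k] = faces(t, k) - 1;
      vf[F[t][k]].push_back(t);
    }
  }

  std::priority_queue<EdgeItem, std::vector<EdgeItem>, LongerFirst> pq;
  auto edgeLen = [&](int a, int b) {
    const double dx = X[a] - X[b], dy = Y[a] - Y[b], dz = Z[a] - Z[b];
    return std::sqrt(dx * dx + dy * dy + dz * dz);
  };
  auto pushFaceEdges = [&](int t) {
    for (int k = 0; k < 3; ++k) {
      int a = F[t][k], b = F[t][(k + 1) % 3];
      if (a > b) std::swap(a, b);
      pq.push(EdgeItem{edgeLen(a, b), a, b, version[a], version[b]});
    }
  };
  for (int t = 0; t < nf; ++t) pushFaceEdges(t);

  int alive = nv;
  while (alive > target && !pq.empty()) {
    EdgeItem e = pq.top();
    pq.pop();
    if (!vAlive[e.u] || !vAlive[e.v]) continue;
    if (version[e.u] != e.vu || version[e.v] != e.vv) continue;
    // confirm the edge still bounds a live face
    bool connected = false;
    for (int t : vf[e.u]) {
      if (!fAlive[t]) continue;
      if (F[t][0] == e.v || F[t][1] == e.v || F[t][2] == e.v) {
        connected = true;
        break;
      }
    }
    if (!connected) continue;

    // collapse v into u at the edge midpoint
    X[e.u] = 0.5 * (X[e.u] + X[e.v]);
    Y[e.u] = 0.5 * (Y[e.u] + Y[e.v]);
    Z[e.u] = 0.5 * (Z[e.u] + Z[e.v]);
    for (int t : vf[e.v]) {
      if (!fAlive[t]) continue;
      bool hasU = (F[t][0] == e.u || F[t][1] == e.u || F[t][2] == e.u);
      if (hasU) {
        fAlive[t] = 0;  // shared face collapses to a sliver
        continue;
      }
      for (int k = 0; k < 3; ++k)
        if (F[t][k] == e.v) F[t][k] = e.u;
      vf[e.u].push_back(t);
    }
    vAlive[e.v] = 0;
    --alive;
    ++version[e.u];

    // compact incidence of u, drop degenerate faces, refresh edges
    std::vector<int> keep;
    keep.reserve(vf[e.u].size());
    for (int t : vf[e.u]) {
      if (!fAlive[t]) continue;
      if (F[t][0] == F[t][1] || F[t][1] == F[t][2] || F[t][0] == F[t][2]) {
        fAlive[t] = 0;
        continue;
      }
      keep.push_back(t);
    }
    vf[e.u].swap(keep);
    for (int t : vf[e.u]) pushFaceEdges(t);
  }

  // compact the result
  std::vector<int> remap(nv, -1);
  int nOut = 0;
  for (int i = 0; i < nv; ++i)
    if (vAlive[i]) remap[i] = nOut++;
  NumericMatrix vOut(nOut, 3);
  for (int i = 0; i < nv; ++i) {
    if (remap[i] < 0) continue;
    vOut(remap[i], 0) = X[i];
    vOut(remap[i], 1) = Y[i];
    vOut(remap[i], 2) = Z[i];
  }
  int mOut = 0;
  for (int t = 0; t < nf; ++t)
    if (fAlive[t]) ++mOut;
  IntegerMatrix fOut(mOut, 3);
  int r = 0;
  for (int t = 0; t < nf; ++t) {
    if (!fAlive[t]) continue;
    for (int k = 0; k < 3; ++k) fOut(r, k) = remap[F[t][k]] + 1;
    ++r;
  }
  return List::create(_["vertices"] = vOut, _["faces"] = fOut);
}
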