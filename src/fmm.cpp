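#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

// Fast marching on a triangulated surface (Kimmel-Sethian triangle update
// with an edge/Dijkstra fallback), plus optional non-manifold "jump" edges
// (inter-atrial connections).  slowness is per-vertex in time per unit
// length; non-finite slowness marks a blocked vertex that is never reached.

namespace {

struct HeapItem {
  double t;
  int v;
  bool operator<(const HeapItem& o) const { return t > o.t; }
};

inline double edist(const NumericMatrix& X, int a, int b) {
  double dx = X(a, 0) - X(b, 0), dy = X(a, 1) - X(b, 1), dz = X(a, 2) - X(b, 2);
  return std::sqrt(dx * dx + dy * dy + dz * dz);
}

// planar wavefront update of vertex C from triangle (A, B, C)
double tri_update(double TA, double TB, double b, double a, double c,
                  double F) {
  // b = |AC|, a = |BC|, c = |AB|; F = slowness at C
  if (TB < TA) { std::swap(TA, TB); std::swap(a, b); }
  double u = TB - TA;
  double costh = (a * a + b * b - c * c) / (2.0 * a * b); // angle at C
  if (costh > 1.0) costh = 1.0;
  if (costh < -1.0) costh = -1.0;
  double sin2 = 1.0 - costh * costh;
  double A2 = a * a + b * b - 2.0 * a * b * costh;
  double B2 = 2.0 * b * u * (a * costh - b);
  double C2 = b * b * (u * u - a * a * F * F * sin2);
  double disc = B2 * B2 - 4.0 * A2 * C2;
  if (disc >= 0.0 && A2 > 0.0) {
    double t = (-B2 + std::sqrt(disc)) / (2.0 * A2);
    if (u < t) {
      double w = b * (t - u) / t;
      if (a * costh < w && (costh <= 0.0 || w < a / costh))
        return TA + t;
    }
  }
  // fallback: Dijkstra-style along the two edges
  return std::min(TA + b * F, TB + a * F);
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_fmm(NumericMatrix verts, IntegerMatrix faces,
                      NumericVector slowness, IntegerMatrix extra_edges,
                      IntegerVector sources, NumericVector t0) {
  const int nv = verts.nrow(), nf = faces.nrow();
  if (slowness.size() != nv) stop("slowness length must equal vertex count");

  // vertex -> incident faces
  std::vector<std::vector<int>> vfaces(nv);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      int v = faces(f, k);
      if (v < 0 || v >= nv) stop("face index out of range");
      vfaces[v].push_back(f);
    }
  // vertex -> extra-edge neighbours
  std::vector<std::vector<int>> vjump(nv);
  for (int e = 0; e < extra_edges.nrow(); ++e) {
    int a = extra_edges(e, 0), b = extra_edges(e, 1);
    if (a < 0 || a >= nv || b < 0 || b >= nv) stop("extra edge out of range");
    vjump[a].push_back(b);
    vjump[b].push_back(a);
  }

  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> T(nv, INF);
  std::vector<char> done(nv, 0);
  std::priority_queue<HeapItem> heap;

  auto blocked = [&](int v) { return !std::isfinite(slowness[v]); };

  // vertex neighbours (for exact near-field source initialization)
  std::vector<std::vector<int>> vnb(nv);
  for (int f = 0; f < nf; ++f)
    for (int k = 0; k < 3; ++k) {
      vnb[faces(f, k)].push_back(faces(f, (k + 1) % 3));
      vnb[faces(f, k)].push_back(faces(f, (k + 2) % 3));
    }

  for (int k = 0; k < sources.size(); ++k) {
    int s = sources[k];
    if (s < 0 || s >= nv) stop("source vertex out of range");
    if (blocked(s)) continue;
    double tt = (t0.size() == sources.size()) ? t0[k] : 0.0;
    if (tt < T[s]) { T[s] = tt; heap.push({tt, s}); }
    // first-order FMM is least accurate near the source (wavefront
    // curvature); initialize a near field of a few rings with
    // straight-line times, but only across homogeneous, unblocked tissue
    const int max_depth = 4;
    std::vector<int> depth(nv, -1);
    std::vector<int> q{s};
    depth[s] = 0;
    size_t qi = 0;
    while (qi < q.size()) {
      int u = q[qi++];
      if (depth[u] == max_depth) continue;
      for (int v : vnb[u]) {
        if (depth[v] >= 0 || blocked(v)) continue;
        if (std::fabs(slowness[v] - slowness[s]) >
            1e-6 * slowness[s]) continue;
        depth[v] = depth[u] + 1;
        q.push_back(v);
        double cand = tt + edist(verts, s, v) * slowness[s];
        if (cand < T[v]) { T[v] = cand; heap.push({cand, v}); }
      }
    }
  }

  auto relax = [&](int v, double cand) {
    if (cand < T[v]) { T[v] = cand; heap.push({cand, v}); }
  };

  while (!heap.empty()) {
    HeapItem it = heap.top(); heap.pop();
    int u = it.v;
    if (done[u] || it.t > T[u]) continue;
    done[u] = 1;
    // triangle updates for all not-yet-accepted vertices of incident faces
    for (int f : vfaces[u]) {
      int vv[3] = {faces(f, 0), faces(f, 1), faces(f, 2)};
      for (int k = 0; k < 3; ++k) {
        int c = vv[k];
        if (done[c] || blocked(c)) continue;
        int a = vv[(k + 1) % 3], b = vv[(k + 2) % 3];
        double F = slowness[c];
        double cand;
        bool finA = std::isfinite(T[a]), finB = std::isfinite(T[b]);
        if (finA && finB)
          cand = tri_update(T[a], T[b], edist(verts, a, c), edist(verts, b, c),
                            edist(verts, a, b), F);
        else if (finA)
          cand = T[a] + edist(verts, a, c) * F;
        else if (finB)
          cand = T[b] + edist(verts, b, c) * F;
        else
          continue;
        relax(c, cand);
      }
    }
    // jump edges: plain edge update with mean slowness
    for (int w : vjump[u]) {
      if (done[w] || blocked(w)) continue;
      double F = 0.5 * (slowness[u] + slowness[w]);
      relax(w, T[u] + edist(verts, u, w) * F);
    }
  }

  NumericVector out(nv);
  for (int v = 0; v < nv; ++v) out[v] = std::isfinite(T[v]) ? T[v] : NA_REAL;
  return out;
}
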