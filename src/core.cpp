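// Voxel-graph primitives shared by the fuzzy-distance and multi-scale
// opening machinery.  All volumes are R arrays in (z, y, x) order, i.e.
// column-major with dim = c(nz, ny, nx); linear indices are 0-based here
// and converted to/from R's 1-based indices at the interface.
//
// 26-adjacency throughout; link lengths are physical (anisotropic voxel
// spacing in micrometres enters every Euclidean step).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

namespace {

struct Grid {
  int nz, ny, nx;
  R_xlen_t n;
  // neighbour offsets as (dz, dy, dx) and precomputed linear shifts / lengths
  std::vector<int> dz, dy, dx;
  std::vector<double> len;
  Grid(IntegerVector dim, NumericVector spacing) {
    nz = dim[0]; ny = dim[1]; nx = dim[2];
    n = (R_xlen_t)nz * ny * nx;
    for (int a = -1; a <= 1; ++a)
      for (int b = -1; b <= 1; ++b)
        for (int c = -1; c <= 1; ++c) {
          if (a == 0 && b == 0 && c == 0) continue;
          dz.push_back(a); dy.push_back(b); dx.push_back(c);
          double l = std::sqrt(a * a * spacing[0] * spacing[0] +
                               b * b * spacing[1] * spacing[1] +
                               c * c * spacing[2] * spacing[2]);
          len.push_back(l);
        }
  }
  inline R_xlen_t idx(int z, int y, int x) const {
    return (R_xlen_t)z + (R_xlen_t)nz * ((R_xlen_t)y + (R_xlen_t)ny * x);
  }
  inline void coords(R_xlen_t i, int &z, int &y, int &x) const {
    z = (int)(i % nz);
    R_xlen_t r = i / nz;
    y = (int)(r % ny);
    x = (int)(r / ny);
  }
  inline bool inside(int z, int y, int x) const {
    return z >= 0 && z < nz && y >= 0 && y < ny && x >= 0 && x < nx;
  }
};

typedef std::pair<double, R_xlen_t> QNode; // (distance, voxel)
typedef std::priority_queue<QNode, std::vector<QNode>, std::greater<QNode> > MinHeap;

const double INF = std::numeric_limits<double>::infinity();

} // namespace

//' @noRd
// [[Rcpp::export(name = ".cpp_fdt")]]
NumericVector cpp_fdt(NumericVector mu, IntegerVector dim, NumericVector spacing) {
  Grid g(dim, spacing);
  NumericVector omega(g.n);
  MinHeap heap;
  // Background voxels (mu <= 0, or outside the array) have distance 0.
  // Support voxels are seeded with the half-link to their cheapest
  // background neighbour, then relaxed by Dijkstra over interior links.
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (mu[i] <= 0) { omega[i] = 0.0; continue; }
    omega[i] = INF;
    int z, y, x; g.coords(i, z, y, x);
    double best = INF;
    for (size_t k = 0; k < g.len.size(); ++k) {
      int zz = z + g.dz[k], yy = y + g.dy[k], xx = x + g.dx[k];
      bool bg = !g.inside(zz, yy, xx) || mu[g.idx(zz, yy, xx)] <= 0;
      if (bg) {
        double w = 0.5 * mu[i] * g.len[k];
        if (w < best) best = w;
      }
    }
    if (best < INF) { omega[i] = best; heap.push(QNode(best, i)); }
  }
  while (!heap.empty()) {
    QNode t = heap.top(); heap.pop();
    R_xlen_t p = t.second;
    if (t.first > omega[p]) continue;
    int z, y, x; g.coords(p, z, y, x);
    for (size_t k = 0; k < g.len.size(); ++k) {
      int zz = z + g.dz[k], yy = y + g.dy[k], xx = x + g.dx[k];
      if (!g.inside(zz, yy, xx)) continue;
      R_xlen_t q = g.idx(zz, yy, xx);
      if (mu[q] <= 0) continue;
      double cand = omega[p] + 0.5 * (mu[p] + mu[q]) * g.len[k];
      if (cand < omega[q]) { omega[q] = cand; heap.push(QNode(cand, q)); }
    }
  }
  return omega;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_geodesic")]]
NumericVector cpp_geodesic(NumericVector mu, IntegerVector dim, NumericVector spacing,
                           IntegerVector sources) {
  // Fuzzy geodesic distance from a source set, propagated inside the
  // support only.  Voxels outside the support (or unreachable) -> Inf.
  Grid g(dim, spacing);
  NumericVector dist(g.n, INF);
  MinHeap heap;
  for (R_xlen_t s = 0; s < sources.size(); ++s) {
    R_xlen_t i = sources[s] - 1; // 1-based from R
    if (i < 0 || i >= g.n) stop("source index out of range");
    dist[i] = 0.0;
    heap.push(QNode(0.0, i));
  }
  while (!heap.empty()) {
    QNode t = heap.top(); heap.pop();
    R_xlen_t p = t.second;
    if (t.first > dist[p]) continue;
    int z, y, x; g.coords(p, z, y, x);
    for (size_t k = 0; k < g.len.size(); ++k) {
      int zz = z + g.dz[k], yy = y + g.dy[k], xx = x + g.dx[k];
      if (!g.inside(zz, yy, xx)) continue;
      R_xlen_t q = g.idx(zz, yy, xx);
      if (mu[q] <= 0) continue;
      double cand = dist[p] + 0.5 * (mu[p] + mu[q]) * g.len[k];
      if (cand < dist[q]) { dist[q] = cand; heap.push(QNode(cand, q)); }
    }
  }
  return dist;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_min_weight_path")]]
List cpp_min_weight_path(NumericVector w, LogicalVector region, IntegerVector dim,
                         int src, int dst) {
  // Path minimising the sum of node weights over the visited voxels
  // (both endpoints included), confined to `region`.  Ties are broken by
  // fewer voxels, then by the smallest predecessor linear index, which
  // fixes a unique path for reproducibility.
  Grid g(dim, NumericVector::create(1.0, 1.0, 1.0));
  R_xlen_t s = (R_xlen_t)src - 1, d = (R_xlen_t)dst - 1;
  if (s < 0 || s >= g.n || d < 0 || d >= g.n) stop("endpoint index out of range");
  if (!region[s] || !region[d]) stop("endpoints must lie inside the region");
  std::vector<double> dist(g.n, INF);
  std::vector<int> hops(g.n, INT_MAX);
  std::vector<R_xlen_t> pred(g.n, -1);
  const double eps = 1e-12;
  typedef std::pair<std::pair<double, int>, R_xlen_t> PQNode; // ((cost,hops),voxel)
  std::priority_queue<PQNode, std::vector<PQNode>, std::greater<PQNode> > heap;
  dist[s] = w[s]; hops[s] = 1;
  heap.push(PQNode(std::make_pair(dist[s], 1), s));
  while (!heap.empty()) {
    PQNode t = heap.top(); heap.pop();
    R_xlen_t p = t.second;
    if (t.first.first > dist[p] + eps ||
        (std::abs(t.first.first - dist[p]) <= eps && t.first.second > hops[p]))
      continue;
    if (p == d) break;
    int z, y, x; g.coords(p, z, y, x);
    for (size_t k = 0; k < g.len.size(); ++k) {
      int zz = z + g.dz[k], yy = y + g.dy[k], xx = x + g.dx[k];
      if (!g.inside(zz, yy, xx)) continue;
      R_xlen_t q = g.idx(zz, yy, xx);
      if (!region[q]) continue;
      double cand = dist[p] + w[q];
      int ch = hops[p] + 1;
      bool better = cand < dist[q] - eps;
      bool tie = !better && cand < dist[q] + eps;
      if (better || (tie && (ch < hops[q] || (ch == hops[q] && p < pred[q])))) {
        dist[q] = better ? cand : dist[q];
        hops[q] = ch; pred[q] = p;
        heap.push(PQNode(std::make_pair(dist[q], ch), q));
      }
    }
  }
  if (!std::isfinite(dist[d])) {
    return List::create(_["path"] = IntegerVector(0), _["cost"] = NA_REAL);
  }
  std::vector<int> rev;
  for (R_xlen_t p = d; p != -1; p = pred[p]) {
    rev.push_back((int)(p + 1));
    if (p == s) break;
  }
  IntegerVector path(rev.rbegin(), rev.rend());
  return List::create(_["path"] = path, _["cost"] = dist[d]);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim) {
  // 26-connected component labelling; labels assigned in raster-scan
  // order of the first voxel encountered (deterministic).
  Grid g(dim, NumericVector::create(1.0, 1.0, 1.0));
  IntegerVector lab(g.n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    lab[i] = ++next;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t p = stack.back(); stack.pop_back();
      int z, y, x; g.coords(p, z, y, x);
      for (size_t k = 0; k < g.len.size(); ++k) {
        int zz = z + g.dz[k], yy = y + g.dy[k], xx = x + g.dx[k];
        if (!g.inside(zz, yy, xx)) continue;
        R_xlen_t q = g.idx(zz, yy, xx);
        if (mask[q] && lab[q] == 0) { lab[q] = next; stack.push_back(q); }
      }
    }
  }
  return lab;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_local_maxima")]]
LogicalVector cpp_local_maxima(NumericVector omega, LogicalVector mask,
                               IntegerVector dim, int l) {
  // p is locally deepest if omega(q) <= omega(p) for every mask voxel q
  // in the (2l+1)^3 neighbourhood (plateaus qualify).
  Grid g(dim, NumericVector::create(1.0, 1.0, 1.0));
  LogicalVector out(g.n, false);
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (!mask[i]) continue;
    int z, y, x; g.coords(i, z, y, x);
    bool deepest = true;
    for (int a = -l; a <= l && deepest; ++a)
      for (int b = -l; b <= l && deepest; ++b)
        for (int c = -l; c <= l && deepest; ++c) {
          int zz = z + a, yy = y + b, xx = x + c;
          if (!g.inside(zz, yy, xx)) continue;
          R_xlen_t q = g.idx(zz, yy, xx);
          if (mask[q] && omega[q] > omega[i]) deepest = false;
        }
    out[i] = deepest;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_mso_grow")]]
List cpp_mso_grow(NumericVector omega_s, NumericVector omega_d,
                  IntegerVector init, NumericVector dist_s, NumericVector dist_d,
                  NumericVector mu, IntegerVector dim, NumericVector spacing,
                  double step) {
  // Scale-synchronised competitive growth.  init: 0 = unclaimed support,
  // 1 = dendrite-claimed, 2 = spine-claimed, 3 = separator (never
  // claimed), -1 = background.  At each scale s (descending from the
  // deepest value to 0 in `step` decrements) both objects expand from
  // their already-claimed voxels through unclaimed voxels whose own
  // initial FDT value is >= s.  Within a scale the two fronts race by
  // fuzzy geodesic distance (competitive multi-source Dijkstra with the
  // usual half-sum membership link lengths): a voxel goes to the object
  // arriving first; on an exact distance tie the object whose seed set is
  // geodesically nearer wins (dist_s / dist_d), dendrite on a full tie.
  // Whatever remains unclaimed at the end (separator-isolated voxels and
  // the separators themselves) is assigned to the dendrite; the count is
  // returned for logging.
  Grid g(dim, spacing);
  IntegerVector lab(clone(init));
  const double eps = 1e-9;
  double smax = 0.0;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (init[i] == -1) continue;
    if (omega_s[i] > smax) smax = omega_s[i];
    if (omega_d[i] > smax) smax = omega_d[i];
  }
  if (step <= 0) stop("scale step must be positive");
  // (distance, (voxel, object)); min-heap ordered by distance then voxel
  // then object (1 before 2), which fixes the pop order deterministically
  typedef std::pair<double, std::pair<R_xlen_t, int> > RNode;
  std::vector<double> arr(g.n);
  double s = smax;
  bool last = false;
  while (true) {
    if (s <= 0) { s = 0.0; last = true; }
    std::priority_queue<RNode, std::vector<RNode>, std::greater<RNode> > heap;
    std::fill(arr.begin(), arr.end(), INF);
    // sources: claimed voxels with at least one claimable neighbour
    for (R_xlen_t i = 0; i < g.n; ++i) {
      if (lab[i] != 1 && lab[i] != 2) continue;
      int z, y, x; g.coords(i, z, y, x);
      const NumericVector &om = (lab[i] == 1) ? omega_d : omega_s;
      for (size_t k = 0; k < g.len.size(); ++k) {
        int zz = z + g.dz[k], yy = y + g.dy[k], xx = x + g.dx[k];
        if (!g.inside(zz, yy, xx)) continue;
        R_xlen_t q = g.idx(zz, yy, xx);
        if (lab[q] != 0 || om[q] < s - eps) continue;
        double w = 0.5 * (mu[i] + mu[q]) * g.len[k];
        heap.push(RNode(w, std::make_pair(q, lab[i])));
      }
    }
    while (!heap.empty()) {
      RNode t = heap.top(); heap.pop();
      R_xlen_t p = t.second.first;
      int obj = t.second.second;
      double d = t.first;
      if (lab[p] != 0) {
        // already claimed this scale; an exact tie by the rival re-opens
        // the seed-distance rule (dendrite preferred on a full tie)
        if (lab[p] != obj && d <= arr[p] + 1e-12) {
          int who = (dist_s[p] < dist_d[p] - eps) ? 2 : 1;
          lab[p] = who;
        }
        continue;
      }
      lab[p] = obj;
      arr[p] = d;
      const NumericVector &om = (obj == 1) ? omega_d : omega_s;
      int z, y, x; g.coords(p, z, y, x);
      for (size_t k = 0; k < g.len.size(); ++k) {
        int zz = z + g.dz[k], yy = y + g.dy[k], xx = x + g.dx[k];
        if (!g.inside(zz, yy, xx)) continue;
        R_xlen_t q = g.idx(zz, yy, xx);
        if (lab[q] != 0 || om[q] < s - eps) continue;
        double w = d + 0.5 * (mu[p] + mu[q]) * g.len[k];
        if (w < arr[q]) heap.push(RNode(w, std::make_pair(q, obj)));
      }
    }
    if (last) break;
    s -= step;
  }
  int forced = 0;
  for (R_xlen_t i = 0; i < g.n; ++i) {
    if (lab[i] == 0 || lab[i] == 3) { lab[i] = 1; ++forced; }
  }
  return List::create(_["labels"] = lab, _["n_forced"] = forced);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_convolve_axis")]]
NumericVector cpp_convolve_axis(NumericVector vol, IntegerVector dim,
                                NumericVector kernel, int axis) {
  // Separable 1-D convolution along one axis (1 = z, 2 = y, 3 = x) with
  // reflect padding (edge value mirrored without repeating the border).
  int nz = dim[0], ny = dim[1], nx = dim[2];
  R_xlen_t n = (R_xlen_t)nz * ny * nx;
  NumericVector out(n);
  int klen = kernel.size();
  int r = (klen - 1) / 2;
  int len = (axis == 1) ? nz : (axis == 2) ? ny : nx;
  R_xlen_t stride = (axis == 1) ? 1 : (axis == 2) ? nz : (R_xlen_t)nz * ny;
  R_xlen_t nlines = n / len;
  std::vector<double> line(len);
  for (R_xlen_t li = 0; li < nlines; ++li) {
    // base index of this line
    R_xlen_t base;
    if (axis == 1) {
      base = li * nz;
    } else if (axis == 2) {
      R_xlen_t z = li % nz, x = li / nz;
      base = z + (R_xlen_t)nz * ny * x;
    } else {
      base = li;
    }
    for (int j = 0; j < len; ++j) line[j] = vol[base + stride * j];
    for (int j = 0; j < len; ++j) {
      double acc = 0.0;
      for (int k = 0; k < klen; ++k) {
        int idx = j + k - r;
        // reflect: -1 -> 1, -2 -> 2, len -> len-2 ...
        while (idx < 0 || idx >= len) {
          if (idx < 0) idx = -idx;
          if (idx >= len) idx = 2 * (len - 1) - idx;
          if (len == 1) { idx = 0; break; }
        }
        acc += kernel[k] * line[idx];
      }
      out[base + stride * j] = acc;
    }
  }
  return out;
}
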