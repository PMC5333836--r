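#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

// Uniform-grid spatial index for point clouds in physical coordinates.
// Used for nearest-surface queries during radius estimation and for the
// fixed-radius neighbour lists that drive the staged linking protocol.

namespace {

struct Grid {
  double h;                      // cell edge
  double mn[3];
  int gd[3];
  std::vector<std::vector<int>> cells;
  const NumericMatrix *pts;

  void build(const NumericMatrix &p, double cell) {
    pts = &p;
    h = cell;
    for (int a = 0; a < 3; ++a) {
      double lo = R_PosInf;
      for (int i = 0; i < p.nrow(); ++i) lo = std::min(lo, p(i, a));
      mn[a] = lo;
    }
    double mx[3];
    for (int a = 0; a < 3; ++a) {
      double hi = R_NegInf;
      for (int i = 0; i < p.nrow(); ++i) hi = std::max(hi, p(i, a));
      mx[a] = hi;
    }
    for (int a = 0; a < 3; ++a)
      gd[a] = std::max(1, (int)std::floor((mx[a] - mn[a]) / h) + 1);
    cells.assign((size_t)gd[0] * gd[1] * gd[2], {});
    for (int i = 0; i < p.nrow(); ++i) cells[cell_of(i)].push_back(i);
  }
  int clampc(double v, int a) const {
    int c = (int)std::floor((v - mn[a]) / h);
    return std::min(std::max(c, 0), gd[a] - 1);
  }
  size_t cidx(int cx, int cy, int cz) const {
    return (size_t)cx + (size_t)gd[0] * ((size_t)cy + (size_t)gd[1] * cz);
  }
  size_t cell_of(int i) const {
    const NumericMatrix &p = *pts;
    return cidx(clampc(p(i, 0), 0), clampc(p(i, 1), 1), clampc(p(i, 2), 2));
  }
  double dist2(const double q[3], int i) const {
    const NumericMatrix &p = *pts;
    double s = 0;
    for (int a = 0; a < 3; ++a) { double d = q[a] - p(i, a); s += d * d; }
    return s;
  }
  // nearest point to q, optionally excluding index `excl`; returns index, best2 = squared dist
  int nearest(const double q[3], int excl, double &best2) const {
    int qc[3] = {clampc(q[0], 0), clampc(q[1], 1), clampc(q[2], 2)};
    best2 = std::numeric_limits<double>::infinity();
    int best = -1;
    int maxr = std::max({gd[0], gd[1], gd[2]});
    for (int r = 0; r <= maxr; ++r) {
      // once a candidate is found, cells at ring r have min distance (r-1)*h
      if (best >= 0 && (double)(r - 1) * h > std::sqrt(best2)) break;
      bool any = false;
      for (int cz = qc[2] - r; cz <= qc[2] + r; ++cz) {
        if (cz < 0 || cz >= gd[2]) continue;
        for (int cy = qc[1] - r; cy <= qc[1] + r; ++cy) {
          if (cy < 0 || cy >= gd[1]) continue;
          for (int cx = qc[0] - r; cx <= qc[0] + r; ++cx) {
            if (cx < 0 || cx >= gd[0]) continue;
            int cheb = std::max({std::abs(cx - qc[0]), std::abs(cy - qc[1]), std::abs(cz - qc[2])});
            if (cheb != r) continue;
            any = true;
            for (int i : cells[cidx(cx, cy, cz)]) {
              if (i == excl) continue;
              double d2 = dist2(q, i);
              if (d2 < best2) { best2 = d2; best = i; }
            }
          }
        }
      }
      if (!any && r > maxr) break;
    }
    return best;
  }
  template <class F>
  void within(const double q[3], double radius, F &&f) const {
    double r2 = radius * radius;
    int lo[3], hi[3];
    for (int a = 0; a < 3; ++a) {
      lo[a] = clampc(q[a] - radius, a);
      hi[a] = clampc(q[a] + radius, a);
    }
    for (int cz = lo[2]; cz <= hi[2]; ++cz)
      for (int cy = lo[1]; cy <= hi[1]; ++cy)
        for (int cx = lo[0]; cx <= hi[0]; ++cx)
          for (int i : cells[cidx(cx, cy, cz)])
            if (dist2(q, i) <= r2) f(i, dist2(q, i));
  }
};

double heuristic_cell(const NumericMatrix &p) {
  double lo[3], hi[3], ext[3];
  for (int a = 0; a < 3; ++a) { lo[a] = R_PosInf; hi[a] = R_NegInf; }
  for (int i = 0; i < p.nrow(); ++i)
    for (int a = 0; a < 3; ++a) {
      lo[a] = std::min(lo[a], p(i, a));
      hi[a] = std::max(hi[a], p(i, a));
    }
  double maxext = 0;
  for (int a = 0; a < 3; ++a) {
    ext[a] = hi[a] - lo[a];
    maxext = std::max(maxext, ext[a]);
  }
  if (maxext <= 0) return 1.0;
  double h = maxext / std::max(1.0, std::cbrt((double)p.nrow()));
  // cap the total number of cells (degenerate flat/linear clouds)
  for (;;) {
    double ncell = 1;
    for (int a = 0; a < 3; ++a)
      ncell *= std::floor(ext[a] / h) + 1;
    if (ncell <= 8.0 * p.nrow() + 64) break;
    h *= 2;
  }
  return h;
}

} // namespace

// For each row of `query`, Euclidean distance to the nearest row of `ref`
// (self never excluded: pass disjoint sets, or use cpp_knn_avg for kNN).
// [[Rcpp::export]]
NumericVector cpp_min_dists(NumericMatrix query, NumericMatrix ref) {
  Grid g;
  g.build(ref, heuristic_cell(ref));
  NumericVector out(query.nrow());
  for (int i = 0; i < query.nrow(); ++i) {
    double q[3] = {query(i, 0), query(i, 1), query(i, 2)};
    double b2;
    g.nearest(q, -1, b2);
    out[i] = std::sqrt(b2);
  }
  return out;
}

// Local vessel radius at every skeleton point: s_min = distance to nearest
// surface point; the surface points within factor*s_min of the skeleton
// point have their own nearest-distance-to-the-skeleton averaged. Falls
// back to s_min when the neighbourhood is empty (flagged in `fallback`).
// [[Rcpp::export]]
List cpp_estimate_radius(NumericMatrix skel, NumericMatrix surf, double factor) {
  Grid gs; gs.build(skel, heuristic_cell(skel));
  Grid gf; gf.build(surf, heuristic_cell(surf));
  int ns = surf.nrow();
  NumericVector surf_to_skel(ns);
  for (int i = 0; i < ns; ++i) {
    double q[3] = {surf(i, 0), surf(i, 1), surf(i, 2)};
    double b2; gs.nearest(q, -1, b2);
    surf_to_skel[i] = std::sqrt(b2);
  }
  int nk = skel.nrow();
  NumericVector smin(nk), radius(nk);
  LogicalVector fallback(nk, false);
  for (int i = 0; i < nk; ++i) {
    double q[3] = {skel(i, 0), skel(i, 1), skel(i, 2)};
    double b2; gf.nearest(q, -1, b2);
    double sm = std::sqrt(b2);
    smin[i] = sm;
    double sum = 0; int cnt = 0;
    gf.within(q, factor * sm + 1e-12, [&](int j, double) { sum += surf_to_skel[j]; ++cnt; });
    if (cnt == 0) { radius[i] = sm; fallback[i] = true; }
    else radius[i] = sum / cnt;
  }
  return List::create(_["radius"] = radius, _["s_min"] = smin, _["fallback"] = fallback);
}

// Average distance to the k-th nearest neighbour (self excluded) for each
// k in `ks`. Exact, brute force per point.
// [[Rcpp::export]]
NumericVector cpp_knn_avg(NumericMatrix pts, IntegerVector ks) {
  int n = pts.nrow();
  int kmax = 0;
  for (int k : ks) kmax = std::max(kmax, k);
  if (n <= kmax) stop("need more than max(ks) points");
  NumericVector acc(ks.size(), 0.0);
  std::vector<double> d2(n);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      double s = 0;
      for (int a = 0; a < 3; ++a) { double d = pts(i, a) - pts(j, a); s += d * d; }
      d2[j] = s;
    }
    d2[i] = std::numeric_limits<double>::infinity();  // exclude self
    std::vector<double> tmp(d2);
    std::partial_sort(tmp.begin(), tmp.begin() + kmax, tmp.end());
    for (int t = 0; t < ks.size(); ++t) acc[t] += std::sqrt(tmp[ks[t] - 1]);
  }
  for (int t = 0; t < ks.size(); ++t) acc[t] /= n;
  return acc;
}

// Sorted (distance, id) neighbour lists within `radius` for every point.
// Returns a list with integer `idx` (1-based) and numeric `dist` per point.
// [[Rcpp::export]]
List cpp_range_neighbors(NumericMatrix pts, double radius) {
  Grid g; g.build(pts, std::max(heuristic_cell(pts), radius / 4));
  int n = pts.nrow();
  List out(n);
  for (int i = 0; i < n; ++i) {
    double q[3] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    std::vector<std::pair<double,int>> hits;
    g.within(q, radius, [&](int j, double d2) {
      if (j != i) hits.push_back({std::sqrt(d2), j});
    });
    std::sort(hits.begin(), hits.end(),
              [](const std::pair<double,int> &a, const std::pair<double,int> &b) {
                return a.first < b.first || (a.first == b.first && a.second < b.second);
              });
    IntegerVector idx(hits.size());
    NumericVector dst(hits.size());
    for (size_t t = 0; t < hits.size(); ++t) { idx[t] = hits[t].second + 1; dst[t] = hits[t].first; }
    out[i] = List::create(_["idx"] = idx, _["dist"] = dst);
  }
  return out;
}
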